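species,family,order,category
Onychostoma barbatulum,Cyprinidae,Cypriniformes,NT
Cyprinidae sp. 01,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 02,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 03,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 04,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 05,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 06,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 07,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 08,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 09,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 10,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 11,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 12,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 13,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 14,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 15,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 16,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 17,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 18,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 19,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 20,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 21,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 22,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 23,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 24,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 25,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 26,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 27,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 28,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 29,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 30,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 31,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 32,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 33,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 34,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 35,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 36,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 37,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 38,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 39,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 40,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 41,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 42,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 43,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 44,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 45,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 46,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 47,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 48,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 49,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 50,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 51,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 52,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 53,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 54,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 55,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 56,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 57,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 58,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 59,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 60,Cyprinidae,Cypriniformes,LC
Cyprinidae sp. 61,Cyprinidae,Cypriniformes,LC
Leptobotia elongata,Cobitidae,Cypriniformes,VU
Cobitidae sp. 01,Cobitidae,Cypriniformes,LC
Cobitidae sp. 02,Cobitidae,Cypriniformes,LC
Cobitidae sp. 03,Cobitidae,Cypriniformes,LC
Cobitidae sp. 04,Cobitidae,Cypriniformes,LC
Cobitidae sp. 05,Cobitidae,Cypriniformes,LC
Cobitidae sp. 06,Cobitidae,Cypriniformes,LC
Cobitidae sp. 07,Cobitidae,Cypriniformes,LC
Balitoridae sp. 01,Balitoridae,Cypriniformes,LC
Balitoridae sp. 02,Balitoridae,Cypriniformes,LC
Balitoridae sp. 03,Balitoridae,Cypriniformes,LC
Balitoridae sp. 04,Balitoridae,Cypriniformes,LC
Balitoridae sp. 05,Balitoridae,Cypriniformes,LC
Balitoridae sp. 06,Balitoridae,Cypriniformes,LC
Myxocyprinus asiaticus,Catostomidae,Cypriniformes,CR
Pseudobagrus pratti,Bagridae,Siluriformes,VU
Bagridae sp. 01,Bagridae,Siluriformes,LC
Bagridae sp. 02,Bagridae,Siluriformes,LC
Bagridae sp. 03,Bagridae,Siluriformes,LC
Bagridae sp. 04,Bagridae,Siluriformes,LC
Bagridae sp. 05,Bagridae,Siluriformes,LC
Bagridae sp. 06,Bagridae,Siluriformes,LC
Siluridae sp. 01,Siluridae,Siluriformes,LC
Siluridae sp. 02,Siluridae,Siluriformes,LC
Siluridae sp. 03,Siluridae,Siluriformes,LC
Sisoridae sp. 01,Sisoridae,Siluriformes,LC
Sisoridae sp. 02,Sisoridae,Siluriformes,LC
Sisoridae sp. 03,Sisoridae,Siluriformes,LC
Liobagrus marginatus,Amblycipitidae,Siluriformes,VU
Amblycipitidae sp. 01,Amblycipitidae,Siluriformes,LC
Clariidae sp. 01,Clariidae,Siluriformes,LC
Siniperca roulei,Percichthyidae,Perciformes,VU
Siniperca obscura,Percichthyidae,Perciformes,NT
Siniperca undulata,Percichthyidae,Perciformes,NT
Percichthyidae sp. 01,Percichthyidae,Perciformes,DD
Percichthyidae sp. 02,Percichthyidae,Perciformes,DD
Percichthyidae sp. 03,Percichthyidae,Perciformes,DD
Odontobutidae sp. 01,Odontobutidae,Perciformes,DD
Odontobutidae sp. 02,Odontobutidae,Perciformes,DD
Odontobutidae sp. 03,Odontobutidae,Perciformes,DD
Gobiidae sp. 01,Gobiidae,Perciformes,DD
Gobiidae sp. 02,Gobiidae,Perciformes,DD
Gobiidae sp. 03,Gobiidae,Perciformes,DD
Belontiidae sp. 01,Belontiidae,Perciformes,DD
Belontiidae sp. 02,Belontiidae,Perciformes,DD
Channidae sp. 01,Channidae,Perciformes,DD
Channidae sp. 02,Channidae,Perciformes,DD
Hemiramphidae sp. 01,Hemiramphidae,Beloniformes,DD
Syngnathidae sp. 01,Syngnathidae,Syngnathiformes,DD
Mastacembelidae sp. 01,Mastacembelidae,Synbranchiformes,DD
Mastacembelidae sp. 02,Mastacembelidae,Synbranchiformes,DD
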