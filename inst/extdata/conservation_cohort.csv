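breed,n_samples,source
FJ,364,Shanghai Qinnong Animal Husbandry Technology Co. Ltd. and Shanghai Songlin Food (Group) Co. Ltd.
MMS,333,Shanghai Jiading Meishan Pig Breeding Centre
PD,397,Shanghai Puhui Superior Seed Breeding Technology Co. Ltd.
SHW,199,Shanghai Academy of Agricultural Sciences Zhuanghang Comprehensive Experimental Station
SW,104,Shanghai Shawutou Agricultural Technology Co. Ltd.
MMS_NEW,54,Shanghai Jiading Meishan Pig Breeding Centre
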