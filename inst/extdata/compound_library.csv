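compound_id,name,target_class,cluster_shift_inh,cluster_shift_rev,cytotox_frac,duct_size_factor
ESL001,(+)-JQ1,BET,0,0,0.05,1.4
ESL002,BET-01,BET,0,0,0.05,1
ESL003,BET-02,BET,0,0,0.05,1
ESL004,BET-03,BET,0,0,0.05,1
ESL005,BET-04,BET,0,0,0.05,1
ESL006,BET-05,BET,0,0,0.05,1
ESL007,IBET151,BET,55,0,0.65,1.4
ESL008,IBET762,BET,0,0,0.1,1.4
ESL009,OTX015,BET,60,0,0.7,1
ESL010,PFI-1,BET,0,0,0.05,1.4
ESL011,DMT-01,DMT,0,0,0.05,1
ESL012,DMT-02,DMT,0,0,0.05,1
ESL013,DMT-03,DMT,0,0,0.05,1
ESL014,DMT-04,DMT,0,0,0.05,1
ESL015,DMT-05,DMT,0,0,0.05,1
ESL016,DMT-06,DMT,0,0,0.05,1
ESL017,DMT-07,DMT,0,0,0.05,1
ESL018,DMT-08,DMT,0,0,0.05,1
ESL019,DMT-09,DMT,0,0,0.05,1
ESL020,DMT-10,DMT,0,0,0.05,1
ESL021,DMT-11,DMT,0,0,0.05,1
ESL022,DMT-12,DMT,0,0,0.05,1
ESL023,HAT-01,HAT,0,0,0.05,1
ESL024,HAT-02,HAT,0,0,0.05,1
ESL025,HAT-03,HAT,0,0,0.05,1
ESL026,HAT-04,HAT,0,0,0.05,1
ESL027,HAT-05,HAT,0,0,0.05,1
ESL028,HAT-06,HAT,0,0,0.05,1
ESL029,HAT-07,HAT,0,0,0.05,1
ESL030,HAT-08,HAT,0,0,0.05,1
ESL031,HAT-09,HAT,0,0,0.05,1
ESL032,HAT-10,HAT,0,0,0.05,1
ESL033,HAT-11,HAT,0,0,0.05,1
ESL034,HAT-12,HAT,0,0,0.05,1
ESL035,HDAC_NAD-01,HDAC_NAD,0,0,0.05,1
ESL036,HDAC_NAD-02,HDAC_NAD,0,0,0.05,1
ESL037,HDAC_NAD-03,HDAC_NAD,0,0,0.05,1
ESL038,HDAC_NAD-04,HDAC_NAD,0,0,0.05,1
ESL039,HDAC_NAD-05,HDAC_NAD,0,0,0.05,1
ESL040,HDAC_NAD-06,HDAC_NAD,0,0,0.05,1
ESL041,HDAC_NAD-07,HDAC_NAD,0,0,0.05,1
ESL042,HDAC_NAD-08,HDAC_NAD,0,0,0.05,1
ESL043,HDAC_NAD-09,HDAC_NAD,0,0,0.05,1
ESL044,HDAC_Zn-01,HDAC_Zn,0,0,0.05,1
ESL045,HDAC_Zn-02,HDAC_Zn,0,0,0.05,1
ESL046,HDAC_Zn-03,HDAC_Zn,0,0,0.05,1
ESL047,HDAC_Zn-04,HDAC_Zn,0,0,0.05,1
ESL048,HDAC_Zn-05,HDAC_Zn,0,0,0.05,1
ESL049,HDAC_Zn-06,HDAC_Zn,0,0,0.05,1
ESL050,HDAC_Zn-07,HDAC_Zn,0,0,0.05,1
ESL051,HDAC_Zn-08,HDAC_Zn,0,0,0.05,1
ESL052,HDAC_Zn-09,HDAC_Zn,0,0,0.05,1
ESL053,HDAC_Zn-10,HDAC_Zn,0,0,0.05,1
ESL054,HDAC_Zn-11,HDAC_Zn,0,0,0.05,1
ESL055,HDAC_Zn-12,HDAC_Zn,0,0,0.05,1
ESL056,HDAC_Zn-13,HDAC_Zn,0,0,0.05,1
ESL057,HDAC_Zn-14,HDAC_Zn,0,0,0.05,1
ESL058,HDAC_Zn-15,HDAC_Zn,0,0,0.05,1
ESL059,HDAC_Zn-16,HDAC_Zn,0,0,0.05,1
ESL060,HDAC_Zn-17,HDAC_Zn,0,0,0.05,1
ESL061,HDAC_Zn-18,HDAC_Zn,0,0,0.05,1
ESL062,HDAC_Zn-19,HDAC_Zn,0,0,0.05,1
ESL063,HDAC_Zn-20,HDAC_Zn,0,0,0.05,1
ESL064,HDAC_Zn-21,HDAC_Zn,0,0,0.05,1
ESL065,HDAC_Zn-22,HDAC_Zn,0,0,0.05,1
ESL066,HDAC_Zn-23,HDAC_Zn,0,0,0.05,1
ESL067,HDAC_Zn-24,HDAC_Zn,0,0,0.05,1
ESL068,HDAC_Zn-25,HDAC_Zn,0,0,0.05,1
ESL069,HDAC_Zn-26,HDAC_Zn,0,0,0.05,1
ESL070,HDAC_Zn-27,HDAC_Zn,0,0,0.05,1
ESL071,HDAC_Zn-28,HDAC_Zn,0,0,0.05,1
ESL072,HDAC_Zn-29,HDAC_Zn,0,0,0.05,1
ESL073,HDAC_Zn-30,HDAC_Zn,0,0,0.05,1
ESL074,HDAC_Zn-31,HDAC_Zn,0,0,0.05,1
ESL075,LAQ824,HDAC_Zn,0,0,0.1,0.7
ESL076,apicidin,HDAC_Zn,50,30,0.1,1
ESL077,tubastatin A,HDAC_Zn,0,55,0.65,1
ESL078,HDM-01,HDM,0,0,0.05,1
ESL079,HDM-02,HDM,0,0,0.05,1
ESL080,HDM-03,HDM,0,0,0.05,1
ESL081,HDM-04,HDM,0,0,0.05,1
ESL082,HDM-05,HDM,0,0,0.05,1
ESL083,HDM-06,HDM,0,0,0.05,1
ESL084,HDM-07,HDM,0,0,0.05,1
ESL085,HDM-08,HDM,0,0,0.05,1
ESL086,HDM-09,HDM,0,0,0.05,1
ESL087,HDM-10,HDM,0,0,0.05,1
ESL088,HDM-11,HDM,0,0,0.05,1
ESL089,HDM-12,HDM,0,0,0.05,1
ESL090,HDM-13,HDM,0,0,0.05,1
ESL091,HDM-14,HDM,0,0,0.05,1
ESL092,HDM-15,HDM,0,0,0.05,1
ESL093,3-deazaneplanocin A,HMT,55,0,0.65,1
ESL094,HMT-01,HMT,0,0,0.05,1
ESL095,HMT-02,HMT,0,0,0.05,1
ESL096,HMT-03,HMT,0,0,0.05,1
ESL097,HMT-04,HMT,0,0,0.05,1
ESL098,HMT-05,HMT,0,0,0.05,1
ESL099,HMT-06,HMT,0,0,0.05,1
ESL100,HMT-07,HMT,0,0,0.05,1
ESL101,HMT-08,HMT,0,0,0.05,1
ESL102,HMT-09,HMT,0,0,0.05,1
ESL103,HMT-10,HMT,0,0,0.05,1
ESL104,HMT-11,HMT,0,0,0.05,1
ESL105,HMT-12,HMT,0,0,0.05,1
ESL106,chaetocin,HMT,60,60,0.05,1
ESL107,PARP-01,PARP,0,0,0.05,1
ESL108,PARP-02,PARP,0,0,0.05,1
ESL109,PARP-03,PARP,0,0,0.05,1
ESL110,PARP-04,PARP,0,0,0.05,1
ESL111,PARP-05,PARP,0,0,0.05,1
ESL112,PARP-06,PARP,0,0,0.05,1
ESL113,PARP-07,PARP,0,0,0.05,1
ESL114,PARP-08,PARP,0,0,0.05,1
ESL115,PARP-09,PARP,0,0,0.05,1
ESL116,PARP-10,PARP,0,0,0.05,1
ESL117,B32B3,other,60,0,0.7,1
ESL118,lestaurtinib,other,0,0,0.05,0.7
ESL119,other-01,other,0,0,0.05,1
ESL120,other-02,other,0,0,0.05,1
ESL121,other-03,other,0,0,0.05,1
ESL122,other-04,other,0,0,0.05,1
ESL123,other-05,other,0,0,0.05,1
ESL124,other-06,other,0,0,0.05,1
ESL125,other-07,other,0,0,0.05,1
ESL126,other-08,other,0,0,0.05,1
ESL127,other-09,other,0,0,0.05,1
ESL128,other-10,other,0,0,0.05,1
ESL129,other-11,other,0,0,0.05,1
ESL130,other-12,other,0,0,0.05,1
ESL131,other-13,other,0,0,0.05,1
ESL132,other-14,other,0,0,0.05,1
ESL133,other-15,other,0,0,0.05,1
ESL134,other-16,other,0,0,0.05,1
ESL135,other-17,other,0,0,0.05,1
ESL136,other-18,other,0,0,0.05,1
ESL137,other-19,other,0,0,0.05,1
ESL138,other-20,other,0,0,0.05,1
ESL139,other-21,other,0,0,0.05,1
ESL140,other-22,other,0,0,0.05,1
ESL141,other-23,other,0,0,0.05,1
ESL142,other-24,other,0,0,0.05,1
ESL143,other-25,other,0,0,0.05,1
ESL144,other-26,other,0,0,0.05,1
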