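county,group
Xiaoshan,other
Yuhang,other
Linping,other
Qiantang,other
Fuyang,other
Linan,other
Tonglu,other
Chunan,mountain_island
Jiande,other
Haishu,other
Jiangbei,other
Beilun,other
Zhenhai,other
Yinzhou,other
Fenghua,other
Xiangshan,other
Ninghai,other
Yuyao,other
Cixi,other
Lucheng,other
Longwan,other
Ouhai,other
Dongtou,mountain_island
Yongjia,other
Pingyang,mountain_island
Cangnan,mountain_island
Wencheng,mountain_island
Taishun,mountain_island
Ruian,other
Yueqing,other
Longgang,other
Nanhu,other
Xiuzhou,other
Jiashan,other
Haiyan,other
Haining,other
Pinghu,other
Tongxiang,other
Wuxing,other
Nanxun,other
Deqing,other
Changxing,other
Anji,other
Yuecheng,other
Keqiao,other
Shangyu,other
Xinchang,other
Zhuji,other
Shengzhou,other
Wucheng,other
Jindong,other
Wuyi,mountain_island
Pujiang,other
Panan,mountain_island
Lanxi,other
Yiwu,other
Dongyang,other
Yongkang,other
Kecheng,other
Qujiang,other
Changshan,mountain_island
Kaihua,other
Longyou,mountain_island
Jiangshan,mountain_island
Dinghai,other
Putuo,mountain_island
Daishan,mountain_island
Shengsi,mountain_island
Jiaojiang,other
Huangyan,other
Luqiao,other
Sanmen,mountain_island
Tiantai,mountain_island
Xianju,mountain_island
Wenling,other
Linhai,other
Yuhuan,other
Liandu,mountain_island
Qingtian,mountain_island
Jinyun,other
Suichang,mountain_island
Songyang,mountain_island
Yunhe,mountain_island
Qingyuan,mountain_island
Jingning,mountain_island
Longquan,mountain_island
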