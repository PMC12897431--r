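area,breed,code
Foreign,Duroc,D
Foreign,Landrace,L
Foreign,Yorkshire,Y
Foreign,Pietrain,P
Foreign,Berkshire,B
Shanghai,Middle Meishan,MMS
Shanghai,Fengjing,FJ
Shanghai,Shawutou,SW
Shanghai,Pudong White,PD
Shanghai,Shanghai White,SHW
Jiangsu,Dongchuan,DC
Jiangsu,Erhualian,EH
Jiangsu,Huaibei,HB
Jiangsu,Hongdenglong,HD
Jiangsu,Shan,SZ
Jiangsu,Jiangquhai,JQ
Jiangsu,Xiaomeishan,SMS
Jiangsu,Mi,MI
Zhejiang,Bihu,BH
Zhejiang,Chuanhua,CA
Zhejiang,Chaluhei,CL
Zhejiang,Jiaxinghei,JX
Zhejiang,Lanxihua,LX
Zhejiang,Jinhuaertouwu,JHL
Zhejiang,Shengxianhua,SH
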