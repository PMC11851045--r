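src,dst
Beijing,Tianjin
Beijing,Hebei
Tianjin,Hebei
Hebei,Shanxi
Hebei,InnerMongolia
Hebei,Liaoning
Hebei,Shandong
Hebei,Henan
Shanxi,InnerMongolia
Shanxi,Shaanxi
Shanxi,Henan
InnerMongolia,Liaoning
InnerMongolia,Jilin
InnerMongolia,Heilongjiang
InnerMongolia,Shaanxi
InnerMongolia,Ningxia
InnerMongolia,Gansu
Liaoning,Jilin
Jilin,Heilongjiang
Shanghai,Jiangsu
Shanghai,Zhejiang
Jiangsu,Zhejiang
Jiangsu,Anhui
Jiangsu,Shandong
Zhejiang,Anhui
Zhejiang,Fujian
Zhejiang,Jiangxi
Anhui,Shandong
Anhui,Henan
Anhui,Hubei
Anhui,Jiangxi
Fujian,Jiangxi
Fujian,Guangdong
Jiangxi,Hunan
Jiangxi,Hubei
Jiangxi,Guangdong
Shandong,Henan
Henan,Shaanxi
Henan,Hubei
Hubei,Shaanxi
Hubei,Chongqing
Hubei,Hunan
Hunan,Chongqing
Hunan,Guizhou
Hunan,Guangxi
Hunan,Guangdong
Guangdong,Guangxi
Guangxi,Guizhou
Guangxi,Yunnan
Chongqing,Shaanxi
Chongqing,Sichuan
Chongqing,Guizhou
Sichuan,Shaanxi
Sichuan,Gansu
Sichuan,Qinghai
Sichuan,Tibet
Sichuan,Yunnan
Sichuan,Guizhou
Guizhou,Yunnan
Yunnan,Tibet
Tibet,Qinghai
Tibet,Xinjiang
Shaanxi,Gansu
Shaanxi,Ningxia
Gansu,Ningxia
Gansu,Qinghai
Gansu,Xinjiang
Qinghai,Xinjiang
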