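Beijing
Tianjin
Hebei
Shanxi
InnerMongolia
Liaoning
Jilin
Heilongjiang
Shanghai
Jiangsu
Zhejiang
Anhui
Fujian
Jiangxi
Shandong
Henan
Hubei
Hunan
Guangdong
Guangxi
Hainan
Chongqing
Sichuan
Guizhou
Yunnan
Tibet
Shaanxi
Gansu
Qinghai
Ningxia
Xinjiang
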