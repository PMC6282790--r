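name,log_pmw,psa,hia_percent,role,reference
Acetaminophen,1.31,49.3,100,validation,Castillo-Garit et al.
Acetylsalicylic acid,1.74,63.6,82,train,Castillo-Garit et al.
Caffeine,0.93,58.4,99,train,Yan et al.
Carbamazepine,2.39,46.3,84,train,Dressman et al.; Varma et al.
Cimetidine,1.97,88.89,68,train,Castillo-Garit et al.; Linnankoski et al.
Diclofenac,2.94,49.3,54,train,Veber et al.
Fenoprofen,2.52,46.5,85,train,Hou et al.
Fluconazole,1.40,81.6,94,train,Newby et al.
Flurbiprofen,2.55,37.3,92,train,Raevsky
Ibuprofen,1.52,37.3,98,validation,Newby et al.
Ketoprofen,1.58,54.4,95,train,Newby et al.
Naproxen,2.37,46.5,94,train,Castillo-Garit et al.
Nicotinic acid,1.55,50.2,94,train,Newby et al.
Phenylbutazone,2.15,40.6,94,train,Hou et al.; Veber et al.
Salicylic acid,1.69,57.5,99,validation,Raevsky
Terbutaline,2.96,72.7,25,train,Gres et al.
Theophylline,1.02,69.3,98,train,Kansy et al.
Zolmitriptan,2.30,57.4,92,train,Newby et al.
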