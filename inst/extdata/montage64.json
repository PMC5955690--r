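{"labels":["T8","FT8","F8","AF8","Fp2","Fpz","Fp1","AF7","F7","FT7","T7","TP7","P7","PO7","O1","Oz","O2","PO8","P8","TP8","AFz","Fz","FCz","Cz","CPz","Pz","POz","Iz","AF3","AF4","F5","F3","F1","F6","F4","F2","FC5","FC3","FC1","FC6","FC4","FC2","C5","C3","C1","C6","C4","C2","CP5","CP3","CP1","CP6","CP4","CP2","P5","P3","P1","P6","P4","P2","PO3","PO4","FT9","FT10"],"ref_labels":["A1","A2"],"lr_pairs":{"T8":"T7","FT8":"FT7","F8":"F7","AF8":"AF7","Fp2":"Fp1","Fpz":"Fpz","Fp1":"Fp2","AF7":"AF8","F7":"F8","FT7":"FT8","T7":"T8","TP7":"TP8","P7":"P8","PO7":"PO8","O1":"O2","Oz":"Oz","O2":"O1","PO8":"PO7","P8":"P7","TP8":"TP7","AFz":"AFz","Fz":"Fz","FCz":"FCz","Cz":"Cz","CPz":"CPz","Pz":"Pz","POz":"POz","Iz":"Iz","AF3":"AF4","AF4":"AF3","F5":"F6","F3":"F4","F1":"F2","F6":"F5","F4":"F3","F2":"F1","FC5":"FC6","FC3":"FC4","FC1":"FC2","FC6":"FC5","FC4":"FC3","FC2":"FC1","C5":"C6","C3":"C4","C1":"C2","C6":"C5","C4":"C3","C2":"C1","CP5":"CP6","CP3":"CP4","CP1":"CP2","CP6":"CP5","CP4":"CP3","CP2":"CP1","P5":"P6","P3":"P4","P1":"P2","P6":"P5","P4":"P3","P2":"P1","PO3":"PO4","PO4":"PO3","FT9":"FT10","FT10":"FT9","A1":"A2","A2":"A1"},"pos":{"T8":[0.951056516295154,0,0.309016994374947],"FT8":[0.904508497187474,0.293892626146237,0.309016994374947],"F8":[0.769420884293813,0.559016994374947,0.309016994374947],"AF8":[0.559016994374947,0.769420884293813,0.309016994374947],"Fp2":[0.293892626146237,0.904508497187474,0.309016994374947],"Fpz":[5.82354159244546e-17,0.951056516295154,0.309016994374947],"Fp1":[-0.293892626146236,0.904508497187474,0.309016994374947],"AF7":[-0.559016994374947,0.769420884293813,0.309016994374947],"F7":[-0.769420884293813,0.559016994374948,0.309016994374947],"FT7":[-0.904508497187474,0.293892626146237,0.309016994374947],"T7":[-0.951056516295154,1.16470831848909e-16,0.309016994374947],"TP7":[-0.904508497187474,-0.293892626146237,0.309016994374947],"P7":[-0.769420884293814,-0.559016994374947,0.309016994374947],"PO7":[-0.559016994374948,-0.769420884293813,0.309016994374947],"O1":[-0.293892626146237,-0.904508497187474,0.309016994374947],"Oz":[-1.74706247773364e-16,-0.951056516295154,0.309016994374947],"O2":[0.293892626146236,-0.904508497187474,0.309016994374947],"PO8":[0.559016994374947,-0.769420884293814,0.309016994374947],"P8":[0.769420884293813,-0.559016994374948,0.309016994374947],"TP8":[0.904508497187474,-0.293892626146237,0.309016994374947],"AFz":[4.95380036308546e-17,0.809016994374947,0.587785252292473],"Fz":[3.59914663902998e-17,0.587785252292473,0.809016994374947],"FCz":[1.89218336521707e-17,0.309016994374947,0.951056516295154],"Cz":[0,0,1],"CPz":[-5.67655009565122e-17,-0.309016994374947,0.951056516295154],"Pz":[-1.079743991709e-16,-0.587785252292473,0.809016994374947],"POz":[-1.48614010892564e-16,-0.809016994374947,0.587785252292473],"Iz":[-1.83697019872103e-16,-1,6.12323399573677e-17],"AF3":[-0.294292017086073,0.830961619830334,0.472117564858963],"AF4":[0.294292017086073,0.830961619830334,0.472117564858963],"F5":[-0.618731272867559,0.619752696108508,0.482781739134701],"F3":[-0.433027429173862,0.645416362854495,0.62922568617528],"F1":[-0.222818402619442,0.63455567819109,0.740061518206133],"F6":[0.618731272867559,0.619752696108508,0.482781739134701],"F4":[0.433027429173862,0.645416362854495,0.62922568617528],"F2":[0.222818402619443,0.63455567819109,0.740061518206133],"FC5":[-0.75646880044391,0.342798105731476,0.55699588208699],"FC3":[-0.543523304109841,0.362291155963971,0.757183951361762],"FC1":[-0.283942950358492,0.35069925312423,0.892404860363177],"FC6":[0.75646880044391,0.342798105731476,0.55699588208699],"FC4":[0.543523304109841,0.362291155963971,0.757183951361762],"FC2":[0.283942950358492,0.35069925312423,0.892404860363177],"C5":[-0.809016994374947,9.90760072617092e-17,0.587785252292473],"C3":[-0.587785252292473,7.19829327805997e-17,0.809016994374947],"C1":[-0.309016994374947,3.78436673043415e-17,0.951056516295154],"C6":[0.809016994374947,0,0.587785252292473],"C4":[0.587785252292473,0,0.809016994374947],"C2":[0.309016994374947,0,0.951056516295154],"CP5":[-0.75646880044391,-0.342798105731476,0.55699588208699],"CP3":[-0.543523304109841,-0.362291155963971,0.757183951361762],"CP1":[-0.283942950358492,-0.35069925312423,0.892404860363177],"CP6":[0.75646880044391,-0.342798105731476,0.55699588208699],"CP4":[0.543523304109841,-0.362291155963971,0.757183951361762],"CP2":[0.283942950358492,-0.35069925312423,0.892404860363177],"P5":[-0.618731272867559,-0.619752696108508,0.482781739134701],"P3":[-0.433027429173862,-0.645416362854494,0.62922568617528],"P1":[-0.222818402619443,-0.63455567819109,0.740061518206133],"P6":[0.618731272867559,-0.619752696108508,0.482781739134701],"P4":[0.433027429173862,-0.645416362854495,0.62922568617528],"P2":[0.222818402619442,-0.63455567819109,0.740061518206133],"PO3":[-0.294292017086073,-0.830961619830334,0.472117564858963],"PO4":[0.294292017086073,-0.830961619830335,0.472117564858963],"FT9":[-0.951056516295154,0.309016994374948,6.12323399573677e-17],"FT10":[0.951056516295154,0.309016994374947,6.12323399573677e-17],"A1":[-0.939692620785908,1.15079156022785e-16,-0.342020143325669],"A2":[0.939692620785908,0,-0.342020143325669]}}
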