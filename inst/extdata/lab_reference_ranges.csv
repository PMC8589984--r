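lab,rule,low,high,mid,scale,spread,severity_slope,missingness
albumin,min,3.5,5,3.8,log,0.15,-0.1,0.3
base_excess,min,-2,2,0,linear,3,-1.5,0.5
bicarbonate,min,22,28,24,log,0.12,-0.06,0.08
calcium,min,8.5,10.5,9.2,log,0.07,-0.03,0.1
chloride,min,96,106,102,log,0.04,-0.01,0.07
fibrinogen,min,200,400,300,log,0.25,-0.1,0.85
hematocrit,min,36,50,40,log,0.12,-0.05,0.06
hemoglobin,min,12,17,13.5,log,0.12,-0.05,0.06
magnesium,min,1.7,2.2,2,log,0.1,-0.03,0.25
ph,min,7.35,7.45,7.4,linear,0.05,-0.04,0.45
phosphate,min,2.5,4.5,3.5,log,0.15,-0.05,0.35
platelets,min,150,400,250,log,0.25,-0.1,0.07
amylase,max,30,110,70,log,0.4,0.2,0.95
bnp,max,0,100,80,log,0.8,0.4,0.88
bilirubin,max,0.1,1.2,0.8,log,0.5,0.25,0.4
bun,max,7,20,16,log,0.35,0.25,0.05
cpk,max,20,200,120,log,0.6,0.3,0.7
lactate,max,0.5,2.2,1.4,log,0.35,0.3,0.55
lipase,max,0,160,80,log,0.5,0.25,0.9
prothrombin_time,max,11,13.5,12.5,log,0.15,0.08,0.45
creatinine,max,0.6,1.3,1,log,0.3,0.2,0.03
troponin,max,0,0.04,0.03,log,0.8,0.35,0.6
glucose,deviant,70,140,110,log,0.25,0.12,0.05
sodium,deviant,135,145,140,linear,4,-1,0.04
wbc,conditional_min,4,11,9,log,0.3,0.15,0.05
neutrophils,conditional_min,2,7.5,5,log,0.35,0.15,0.4
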