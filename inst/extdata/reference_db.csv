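name,formula,neutral_mass,class
myristic acid,C14H28O2,228.20893,fatty acid
palmitoleic acid,C16H30O2,254.22458,fatty acid
palmitic acid,C16H32O2,256.24023,fatty acid
heptadecanoic acid,C17H34O2,270.25588,fatty acid
linoleic acid,C18H32O2,280.24023,fatty acid
oleic acid,C18H34O2,282.25588,fatty acid
stearic acid,C18H36O2,284.27153,fatty acid
arachidonic acid,C20H32O2,304.24023,fatty acid
eicosapentaenoic acid,C20H30O2,302.22458,fatty acid
docosahexaenoic acid,C22H32O2,328.24023,fatty acid
cholesterol,C27H46O,386.35486,cholesterol
cholesteryl sulfate,C27H46O4S,466.31166,cholesterol
PA(34:1),C37H71O8P,674.48859,phospholipid
PE(34:1),C39H76NO8P,717.53084,phospholipid
PE(36:2),C41H78NO8P,743.54649,phospholipid
PE(38:4),C43H78NO8P,767.54649,phospholipid
PS(36:1),C42H80NO10P,789.55200,phospholipid
PG(34:1),C40H77O10P,748.52542,phospholipid
PI(38:4),C47H83O13P,886.55712,phospholipid
PC(32:0),C40H80NO8P,733.56214,phospholipid
PC(34:1),C42H82NO8P,759.57779,phospholipid
PC(36:4),C44H80NO8P,781.56214,phospholipid
PC(36:2),C44H84NO8P,785.59344,phospholipid
PC(36:1),C44H86NO8P,787.60909,phospholipid
ceramide d18:1/16:0,C34H67NO3,537.51209,ceramide
ceramide d18:1/24:1,C42H81NO3,647.62164,ceramide
unassigned m/z 309.2036 ES+,unknown,308.19632,metabolite
unassigned m/z 441.2975 ES+,unknown,440.29022,metabolite
unassigned m/z 457.2715 ES+,unknown,456.26422,metabolite
unassigned m/z 469.3288 ES+,unknown,468.32152,metabolite
unassigned m/z 621.4855 ES+,unknown,620.47822,glyceride
unassigned m/z 621.4878 ES+,unknown,620.48052,glyceride
unassigned m/z 649.5168 ES+,unknown,648.50952,glyceride
unassigned m/z 649.5191 ES+,unknown,648.51182,glyceride
unassigned m/z 713.4518 ES+,unknown,712.44452,phospholipid
unassigned m/z 723.4935 ES+,unknown,722.48622,phospholipid
unassigned m/z 739.4675 ES+,unknown,738.46022,phospholipid
unassigned m/z 798.54077 ES+,unknown,797.53349,phospholipid
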