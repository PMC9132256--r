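code,descriptor,category,medicare,private
72148,MRI lumbar spine w/o contrast,ancillary,224.52,NA
72158,MRI lumbar spine w/wo contrast,ancillary,378.41,NA
72132,CT lumbar spine w/ contrast,ancillary,231.01,NA
72131,CT lumbar spine w/o contrast,ancillary,182.36,NA
72133,CT lumbar spine w/wo contrast,ancillary,272.46,NA
62322,Epidural steroid injection,ancillary,88.66,NA
97110,Physical therapy,ancillary,31.35,NA
99213,Office visit,ancillary,51.90,NA
DRG460,Facility fee index inpatient,index,24459,NA
APC_INDEX,Facility fee index outpatient,index,18344.25,NA
63047,Laminectomy,index,1152,NA
22840,Posterior instrumentation,index,800,NA
22853,Insertion of biomechanical device,index,272,NA
20931,Allograft,index,117,NA
77003,Fluoroscopy,index,100,NA
DRG459,Facility fee revision,revision,40822,NA
22850,Removal of device,revision,758,NA
22840,Posterior instrumentation,revision,800,NA
22853,Insertion of biomechanical device,revision,272,NA
20931,Allograft,revision,117,NA
77003,Fluoroscopy,revision,100,NA
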