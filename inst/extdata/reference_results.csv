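perspective,horizon_months,arm,cost,qaly
health_system,3,TOPS,41513,0.1759
health_system,12,TOPS,43445,0.7171
health_system,24,TOPS,44763,1.4142
health_system,72,TOPS,49349,4.0382
health_system,120,TOPS,53320,6.3865
health_system,3,TLIF,40032,0.1697
health_system,12,TLIF,42409,0.7003
health_system,24,TLIF,44462,1.3653
health_system,72,TLIF,56076,3.6848
health_system,120,TLIF,68867,5.6009
societal,3,TOPS,41769,0.1759
societal,12,TOPS,45170,0.7171
societal,24,TOPS,48330,1.4142
societal,72,TOPS,58608,4.0382
societal,120,TOPS,67075,6.3865
societal,3,TLIF,40419,0.1697
societal,12,TLIF,44742,0.7003
societal,24,TLIF,50162,1.3653
societal,72,TLIF,81771,3.6848
societal,120,TLIF,118371,5.6009
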