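attribute,group,M,P,A,I,R,Q,importance
practicality,A,127,42,10,7,2,3,0.88
risk_adequacy,A,127,48,2,9,1,4,0.87
ethical_soundness,A,120,40,8,19,1,3,0.85
legal_conformity,A,148,27,2,13,0,1,0.89
content_validity,A,139,42,1,7,0,2,0.91
technical_adequacy,A,83,68,20,18,2,0,0.82
usability,A,103,49,20,17,0,2,0.84
resource_efficiency,A,63,40,45,40,1,2,0.68
transparency,A,103,43,18,23,3,1,0.79
practicality,B,122,48,4,12,2,3,0.88
risk_adequacy,B,127,46,0,7,3,8,0.88
ethical_soundness,B,123,33,7,23,0,5,0.83
legal_conformity,B,146,20,5,15,1,4,0.86
content_validity,B,140,38,5,6,0,2,0.94
technical_adequacy,B,89,59,24,16,1,2,0.83
usability,B,105,50,16,15,0,5,0.84
resource_efficiency,B,69,37,34,40,6,5,0.71
transparency,B,89,45,22,27,1,7,0.79
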