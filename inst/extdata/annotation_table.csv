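name,formula,adducts,reported_mz,comment
Xanthurenic acid 8-O-sulfate,C10H7NO7S,M+Na;M+2Na-H,307.97,M+Na computes to ~307.9835 Da (~44 ppm above the commonly quoted 307.97); annotation tentative
Inosine monophosphate (IMP),C10H13N4O8P,M+K,387.01,
PA C36:3,C39H71O8P,M+K,737.45,
PA C38:5,C41H71O8P,M+K,761.45,
PA C38:4,C41H73O8P,M+K,763.46,
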