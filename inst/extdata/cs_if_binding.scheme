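# TSA binding with conformational selection and induced fit (HG3.17-like).
# Enzyme states: I (inactive), A (active), AL (complex), ALs (post
# induced-fit complex); L is the free transition-state analogue.
scheme: cs_if_binding
unit: M
species: I A L AL ALs
reaction: I <-> A : k_ia, k_ai
reaction: A + L <-> AL : k_on, k_off
reaction: AL <-> ALs : k_if, k_ir
rate: k_ia = 3.8e-4
rate: k_ai = 2e-05
rate: k_on = 1e+06
rate: k_off = 4.4
rate: k_if = 2
rate: k_ir = 1
observable: fluor : I=1 A=1 AL=0.6 ALs=0.45 : baseline=0
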