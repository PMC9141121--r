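arch,term,coefficient
upper,a,-1.89309451393284e-9
upper,b,3.87447065552008e-7
upper,c,-0.305120626818607e-4
upper,d,0.115143861398714e-2
upper,e,-0.0207466264631038
upper,f,0.142773204710058
upper,g,0
lower,a,-1.40083194030139e-9
lower,b,3.04238736235189e-7
lower,c,-0.254032635123737e-4
lower,d,0.102066672881550e-2
lower,e,-0.0197861695057057
lower,f,0.149264732878305
lower,g,0
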