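# Storage-retrieval MPT model for a recognition + cued-recall test of
# 20 target and 20 distractor words.
# Parameters: s = target storage, r1 = recognition retrieval,
# r2 = cued-recall retrieval, g = probability of guessing "old",
# d = distractor detection (usually constrained to d = s*r1).
11
target Rn+Rc+ s*r1*r2
target Rn+Rc- s*r1*(1-r2)
target Rn+Rc+ s*(1-r1)*g*r2
target Rn+Rc- s*(1-r1)*g*(1-r2)
target Rn-Rc+ s*(1-r1)*(1-g)*r2
target Rn-Rc- s*(1-r1)*(1-g)*(1-r2)
target Rn+Rc- (1-s)*g
target Rn-Rc- (1-s)*(1-g)
distractor D+ d
distractor D- (1-d)*g
distractor D+ (1-d)*(1-g)
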