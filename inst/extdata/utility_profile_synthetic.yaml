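# SYNTHETIC placeholder utility-mapping coefficients.
# The published utility regression this profile stands in for is not
# redistributed here; these values only have plausible signs and magnitudes
# (worse WOMAC scores, higher age and longer disease duration lower the
# utility) and are meant for tests and synthetic trials. Transcribe the real
# coefficients into a profile of the same shape for substantive analyses.
source: synthetic-placeholder
intercept: 0.85
pain: -0.012
function: -0.004
stiffness: -0.008
age: -0.0015
years_since_oa: -0.002
female: -0.01
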