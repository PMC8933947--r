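model_id,n,low,intermediate,high,statin_eligible
pce,1345,588,200,557,563
apce,1345,813,164,368,408
framingham_lipids,1345,776,327,242,344
framingham_bmi,1345,689,360,296,362
who_lipids,1345,685,627,33,33
who_bmi,1345,678,643,24,24
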