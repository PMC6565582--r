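patient	region	inheritance
Patient_1	chr22:18,938,160–21,505,425	maternal
Patient_2	chr22:18,890,264–21,464,056	unknown
Patient_3	chr22:18,890,264–21,461,788	de novo
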