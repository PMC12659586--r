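year,numerator,denominator
2015,2032,137828
2024,20431,178510
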