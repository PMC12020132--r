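parts	canonical
renal function	renal_function
liver enzyme	liver_enzyme
laboratory test	laboratory_test
oral administration	oral_administration
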