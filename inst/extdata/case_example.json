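{"cancer_group":"DIG","sex":"male","birth_year":1952,"diagnosis_year":2010,"exposures":[{"year":1985,"dose":{"dist":"lognormal","gm":120,"gsd":1.4},"duration_hours":1600,"radiation_class":"lowLET","organ_class":"internal"},{"year":1992,"dose":{"dist":"fixed","value":40},"duration_hours":null,"radiation_class":"lowLET","organ_class":"internal"}],"smoking":null}
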