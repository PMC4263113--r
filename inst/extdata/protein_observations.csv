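"observable_name","point","value","replicate_id"
"S","l",1.1428,1
"ESS","l",0.0027,1
"P","l",13.8571,1
"S","u",6.8362,1
"ESS","u",0.0094,1
"P","u",8.1637,1
"stimulus","l",0.007079,1
"stimulus","u",0.010973,1
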