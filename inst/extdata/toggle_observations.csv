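"observable_name","point","value","replicate_id"
"P1","l",1.3714,1
"G2P1","l",0.0012,1
"P2","l",1.018,1
"P1","u",0.1042,1
"G2P1","u",0.0079,1
"P2","u",25.5575,1
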