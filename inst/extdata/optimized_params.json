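{"gamma":1.55e-3,"mu":5.09e-5,"r":1.539,"R":3.417,"S":0.780,"kappa_star":20,"kappa_T":25,"w0":20}
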