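{"scenario":"tiny","seed":1,"n_sites":12,"pool_size":15,"effects":{"intercept":-0.5,"metric":-0.2,"traits":[0.02,-0.96,-0.54,-0.17],"interactions":[0.31,0,0,0]},"variances":{"site":0.25,"category":0.1,"species":1,"spatial":0.25}}
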