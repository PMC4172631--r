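"observer","oo","os","so","ss"
1,37,43,42,38
2,35,45,38,42
3,42,38,39,41
4,46,34,38,42
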