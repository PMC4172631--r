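"anatomy","arm","dose_mas","sd_hu"
"shoulder girdle","original",80,36.4
"shoulder girdle","original",60,38.2
"shoulder girdle","original",40,68.7
"shoulder girdle","original",20,117.6
"shoulder girdle","original",10,174.3
"shoulder girdle","simulation",80,38.7
"shoulder girdle","simulation",60,40.2
"shoulder girdle","simulation",40,68.7
"shoulder girdle","simulation",20,115
"shoulder girdle","simulation",10,173.2
"dorsum","original",80,27
"dorsum","original",60,27.9
"dorsum","original",40,36.6
"dorsum","original",20,57.2
"dorsum","original",10,108.3
"dorsum","simulation",80,27.1
"dorsum","simulation",60,28.8
"dorsum","simulation",40,33.7
"dorsum","simulation",20,58.8
"dorsum","simulation",10,109.9
"abdominal wall","original",80,20.4
"abdominal wall","original",60,24.2
"abdominal wall","original",40,29.5
"abdominal wall","original",20,32.2
"abdominal wall","original",10,66.3
"abdominal wall","simulation",80,20.5
"abdominal wall","simulation",60,25.5
"abdominal wall","simulation",40,28.7
"abdominal wall","simulation",20,36.2
"abdominal wall","simulation",10,65.3
"pelvis","original",80,70.3
"pelvis","original",60,76.7
"pelvis","original",40,94.1
"pelvis","original",20,134
"pelvis","original",10,206.3
"pelvis","simulation",80,68.7
"pelvis","simulation",60,77.5
"pelvis","simulation",40,98.5
"pelvis","simulation",20,130.4
"pelvis","simulation",10,204.5
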