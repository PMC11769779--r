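child,parent
363346000,404684003
372130007,363346000
254701007,372130007
372244006,372130007
93880001,363346000
363406005,363346000
254837009,363346000
399068003,363346000
118600007,363346000
93143009,363346000
91861009,93143009
363418001,363346000
84114007,404684003
42343007,84114007
10633002,42343007
85232009,84114007
128404006,84114007
703272007,84114007
446221000,84114007
413839001,404684003
13645005,413839001
87433001,13645005
185086009,13645005
195967001,413839001
51615001,413839001
190905008,413839001
233703007,413839001
38341003,404684003
73211009,404684003
13644009,404684003
49436004,404684003
414545008,404684003
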