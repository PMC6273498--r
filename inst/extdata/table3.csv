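id,heart,liver,spleen,lung,kidney,brain,stomach,small_intestine
TAX,1,1,1,1,1,1,1,1
M2,0,1,0,1,1,1,1,1
M5,0,1,0,0,1,0,1,0
M7,0,0,0,0,0,0,0,1
M11,1,1,1,1,1,0,1,1
M18,1,1,1,1,1,0,1,1
M19,1,1,1,1,1,0,1,1
M20,0,0,1,1,1,0,1,1
M21,0,1,1,1,1,0,1,1
M22,1,0,0,0,0,0,0,0
M23,0,1,0,0,1,0,1,1
M24,0,1,0,0,0,0,0,1
M25,0,1,0,0,1,0,1,1
M28,0,0,0,0,1,0,1,0
M29,0,0,0,0,0,0,0,1
M30,0,0,0,0,1,0,1,1
M31,0,0,0,0,0,0,1,1
M32,0,1,0,0,1,0,0,1
M33,1,1,1,1,1,1,1,1
M34,0,1,1,1,1,1,1,1
M35,0,1,0,0,1,0,1,1
M36,0,0,0,0,0,0,1,0
M42,0,1,0,0,1,0,1,0
M43,1,0,1,1,0,0,0,1
M44,0,1,0,0,1,0,1,0
M45,0,1,0,0,1,0,1,1
M48,0,1,0,1,1,0,1,1
M49,1,1,1,1,1,0,1,1
M50,0,1,1,1,1,0,1,1
M51,0,0,0,0,0,0,0,1
M52,0,1,0,0,1,0,1,1
M65,0,0,0,0,0,0,1,1
M70,0,0,0,0,0,0,1,1
M72,0,0,0,0,1,0,0,1
M75,0,0,0,0,1,0,0,1
M80,0,0,0,0,1,0,0,1
M84,0,1,0,0,1,0,1,1
M86,0,0,0,0,1,0,0,0
M87,0,0,0,0,0,0,0,1
M91,0,0,0,0,0,0,0,1
M105,0,1,0,0,1,0,1,1
M109,0,0,0,0,1,0,0,1
M118,0,0,0,0,0,0,0,1
M150,0,0,0,0,1,0,0,0
M151,0,0,0,0,1,0,0,0
M161,0,0,0,0,0,0,1,0
M162,0,0,0,0,0,0,1,0
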