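id,reactions
M1,isomerization
M2,isomerization
M3,sulphation
M4,sulphation
M5,sulphation
M6,sulphation
M7,sulphation
M8,sulphation
M9,sulphation
M10,sulphation
M11,sulphation
M12,sulphation;sulphation
M13,sulphation;sulphation
M14,sulphation;sulphation
M15,sulphation;sulphation
M16,sulphation;pyroglutamate_conjugation
M17,glucuronidation
M18,glucuronidation
M19,glucuronidation
M20,glucuronidation
M21,glucuronidation
M22,glucuronidation
M23,glucuronidation
M24,glucuronidation
M25,glucuronidation
M26,hydroxylation;sulphation;glucuronidation
M27,hydroxylation;sulphation;glucuronidation
M28,hydroxylation;sulphation;glucuronidation
M29,hydroxylation;sulphation;glucuronidation
M30,hydroxylation;sulphation;glucuronidation
M31,hydroxylation;sulphation;glucuronidation
M32,hydroxylation;sulphation;glucuronidation
M33,methylation
M34,methylation
M35,methylation
M36,methylation
M37,methylation;sulphation
M38,methylation;sulphation
M39,methylation;sulphation
M40,methylation;sulphation
M41,methylation;sulphation
M42,methylation;sulphation
M43,methylation;sulphation
M44,methylation;sulphation
M45,methylation;sulphation
M46,methylation;sulphation
M47,methylation;glucuronidation
M48,methylation;glucuronidation
M49,methylation;glucuronidation
M50,methylation;glucuronidation
M51,methylation;glucuronidation
M52,methylation;glucuronidation
M53,methylation;glucuronidation
M54,methylation;glucuronidation
M55,methylation;glucuronidation
M56,methylation;sulphation;glucuronidation
M57,methylation;sulphation;glucuronidation
M58,methylation;pyroglutamate_conjugation
M59,methylation;pyroglutamate_conjugation
M60,hydroxylation;methylation;sulphation
M61,hydroxylation;methylation;sulphation
M62,hydroxylation;methylation;sulphation
M63,hydroxylation;methylation;sulphation
M64,hydroxylation;hydroxylation;methylation
M65,hydroxylation;hydroxylation;methylation
M66,hydroxylation;hydroxylation;methylation;glucuronidation
M67,hydroxylation;hydroxylation;methylation;glucuronidation
M68,hydroxylation;hydroxylation;methylation;glucuronidation
M69,hydroxylation;hydroxylation;methylation;glucuronidation
M70,dehydrogenation
M71,dehydrogenation;sulphation
M72,dehydrogenation;sulphation
M73,dehydrogenation;sulphation
M74,dehydrogenation;sulphation
M75,dehydrogenation;sulphation
M76,dehydrogenation;glucuronidation
M77,dehydrogenation;methylation
M78,dehydrogenation;methylation
M79,dehydrogenation;methylation
M80,dehydrogenation;methylation;sulphation
M81,dehydrogenation;methylation;sulphation
M82,dehydrogenation;methylation;sulphation
M83,dehydrogenation;methylation;sulphation
M84,dehydrogenation;methylation;sulphation
M85,dehydrogenation;methylation;sulphation;sulphation;glucuronidation
M86,dehydrogenation;methylation;glucuronidation
M87,dehydrogenation;methylation;glucuronidation
M88,dehydrogenation;methylation;sulphation;glucuronidation
M89,dehydrogenation;methylation;sulphation;glucuronidation
M90,dehydrogenation;methylation;sulphation;glucuronidation
M91,dehydrogenation;methylation;sulphation;glucuronidation
M92,hydroxylation;dehydrogenation;sulphation
M93,hydroxylation;dehydrogenation;sulphation
M94,hydroxylation;dehydrogenation;sulphation
M95,hydroxylation;dehydrogenation;glucuronidation
M96,hydroxylation;dehydrogenation;glucuronidation
M97,hydroxylation;dehydrogenation;methylation;sulphation
M98,hydroxylation;dehydrogenation;methylation;sulphation
M99,hydroxylation;dehydrogenation;methylation;sulphation
M100,hydroxylation;dehydrogenation;methylation;sulphation
M101,hydroxylation;dehydrogenation;methylation;glucuronidation
M102,hydroxylation;dehydrogenation;methylation;glucuronidation
M103,hydroxylation;dehydrogenation;methylation;glucuronidation
M104,dehydroxylation
M105,dehydroxylation
M106,dehydroxylation;sulphation
M107,dehydroxylation;sulphation
M108,dehydroxylation;sulphation
M109,dehydroxylation;sulphation
M110,dehydroxylation;glucuronidation
M111,dehydroxylation;glucuronidation
M112,dehydroxylation;glucuronidation
M113,dehydration;glucuronidation
M114,dehydration;glucuronidation
M115,dehydration;glucuronidation
M116,dehydration;methylation;glucuronidation
M117,hydrogenation
M118,hydrogenation;methylation
M119,hydrogenation;sulphation
M120,hydrogenation;sulphation
M121,hydrogenation;sulphation
M122,ring_cleavage;sulphation
M123,ring_cleavage;sulphation
M124,ring_cleavage;sulphation
M125,ring_cleavage;sulphation
M126,ring_cleavage;glucuronidation
M127,ring_cleavage;glucuronidation
M128,ring_cleavage;sulphation
M129,ring_cleavage;sulphation
M130,ring_cleavage;sulphation
M131,ring_cleavage;sulphation
M132,ring_cleavage;sulphation
M133,ring_cleavage;sulphation
M134,ring_cleavage;sulphation
M135,ring_cleavage;sulphation
M136,ring_cleavage;sulphation
M137,ring_cleavage;sulphation
M138,ring_cleavage;sulphation
M139,ring_cleavage;acetylamination
M140,ring_cleavage;acetylamination
M141,ring_cleavage;acetylamination
M142,ring_cleavage;sulphation
M143,ring_cleavage;sulphation
M144,ring_cleavage;sulphation
M145,ring_cleavage;sulphation
M146,ring_cleavage;sulphation
M147,ring_cleavage;sulphation
M148,ring_cleavage;sulphation
M149,ring_cleavage;sulphation
M150,ring_cleavage;glucuronidation
M151,ring_cleavage;glucuronidation
M152,ring_cleavage;sulphation;glucuronidation
M153,ring_cleavage;sulphation;glucuronidation
M154,ring_cleavage;sulphation
M155,ring_cleavage;sulphation
M156,ring_cleavage;sulphation
M157,ring_cleavage;sulphation
M158,ring_cleavage;sulphation
M159,ring_cleavage;sulphation
M160,dehydroxylation;polymerization;methylation
M161,polymerization;methylation
M162,polymerization;methylation
M163,polymerization;methylation;methylation
M164,polymerization;methylation;sulphation
M165,polymerization;methylation;sulphation
M166,polymerization;methylation;sulphation
M167,polymerization;methylation;methylation;sulphation
M168,polymerization;methylation;methylation;sulphation
M169,polymerization;methylation;methylation;sulphation
M170,dehydroxylation;polymerization;methylation;methylation
M171,dehydroxylation;polymerization;methylation;methylation
M172,dehydroxylation;polymerization;methylation;methylation
M173,dehydrogenation;polymerization;methylation;methylation
M174,dehydrogenation;polymerization;methylation;methylation
M175,dehydrogenation;polymerization;methylation;methylation
M176,dehydrogenation;polymerization;methylation;methylation
M177,dehydroxylation;polymerization;methylation;methylation;methylation
M178,dehydroxylation;polymerization;methylation;methylation;methylation
M179,dehydroxylation;polymerization;methylation;methylation;methylation
M180,polymerization;methylation;methylation
M181,polymerization;methylation;methylation
M182,dehydrogenation;polymerization;methylation;methylation;methylation
M183,dehydrogenation;polymerization;methylation;methylation;methylation
M184,polymerization;methylation;methylation;methylation
M185,polymerization;methylation;methylation;methylation
M186,polymerization;methylation;methylation;methylation
M187,polymerization;methylation;methylation;methylation
M188,polymerization;methylation;methylation;methylation
M189,polymerization;methylation;methylation;methylation
M190,polymerization;methylation;methylation;methylation
M191,dehydroxylation;polymerization;methylation;methylation
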