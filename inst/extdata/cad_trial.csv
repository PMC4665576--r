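subject_id,gold,mdcta
p001,1,1
p002,1,1
p003,1,1
p004,1,1
p005,1,1
p006,1,1
p007,1,1
p008,1,1
p009,1,1
p010,1,1
p011,1,1
p012,1,1
p013,1,1
p014,1,1
p015,1,1
p016,1,1
p017,1,1
p018,1,1
p019,1,1
p020,1,1
p021,1,1
p022,1,1
p023,1,1
p024,1,1
p025,1,1
p026,1,1
p027,1,1
p028,1,1
p029,1,1
p030,1,1
p031,1,1
p032,1,1
p033,1,1
p034,1,1
p035,1,1
p036,1,1
p037,1,1
p038,1,1
p039,1,1
p040,1,1
p041,1,1
p042,1,1
p043,1,1
p044,1,1
p045,1,1
p046,1,1
p047,1,1
p048,1,1
p049,1,1
p050,1,1
p051,1,1
p052,1,1
p053,1,1
p054,1,1
p055,1,1
p056,1,1
p057,1,1
p058,1,1
p059,1,1
p060,1,1
p061,1,1
p062,1,1
p063,1,1
p064,1,1
p065,1,1
p066,1,1
p067,1,1
p068,1,1
p069,1,1
p070,1,1
p071,1,1
p072,1,1
p073,1,1
p074,1,1
p075,1,1
p076,1,1
p077,1,1
p078,1,1
p079,1,1
p080,1,1
p081,1,1
p082,1,1
p083,1,1
p084,1,1
p085,1,1
p086,1,1
p087,1,1
p088,1,1
p089,1,1
p090,1,1
p091,1,1
p092,1,1
p093,1,1
p094,1,1
p095,1,1
p096,1,1
p097,1,1
p098,1,1
p099,1,1
p100,1,1
p101,1,1
p102,1,1
p103,1,1
p104,1,1
p105,1,1
p106,1,1
p107,1,1
p108,1,1
p109,1,1
p110,1,1
p111,1,1
p112,1,1
p113,1,1
p114,1,1
p115,1,1
p116,1,1
p117,1,1
p118,1,1
p119,1,1
p120,1,1
p121,1,1
p122,1,1
p123,1,1
p124,1,1
p125,1,1
p126,1,1
p127,1,1
p128,1,1
p129,1,1
p130,1,1
p131,1,1
p132,1,1
p133,1,1
p134,1,1
p135,1,1
p136,1,1
p137,1,1
p138,1,1
p139,1,1
p140,1,1
p141,0,1
p142,0,1
p143,0,1
p144,0,1
p145,0,1
p146,0,1
p147,0,1
p148,0,1
p149,0,1
p150,0,1
p151,0,1
p152,0,1
p153,0,1
p154,1,0
p155,1,0
p156,1,0
p157,1,0
p158,1,0
p159,1,0
p160,1,0
p161,1,0
p162,1,0
p163,1,0
p164,1,0
p165,1,0
p166,1,0
p167,1,0
p168,1,0
p169,1,0
p170,1,0
p171,1,0
p172,1,0
p173,1,0
p174,1,0
p175,1,0
p176,1,0
p177,1,0
p178,0,0
p179,0,0
p180,0,0
p181,0,0
p182,0,0
p183,0,0
p184,0,0
p185,0,0
p186,0,0
p187,0,0
p188,0,0
p189,0,0
p190,0,0
p191,0,0
p192,0,0
p193,0,0
p194,0,0
p195,0,0
p196,0,0
p197,0,0
p198,0,0
p199,0,0
p200,0,0
p201,0,0
p202,0,0
p203,0,0
p204,0,0
p205,0,0
p206,0,0
p207,0,0
p208,0,0
p209,0,0
p210,0,0
p211,0,0
p212,0,0
p213,0,0
p214,0,0
p215,0,0
p216,0,0
p217,0,0
p218,0,0
p219,0,0
p220,0,0
p221,0,0
p222,0,0
p223,0,0
p224,0,0
p225,0,0
p226,0,0
p227,0,0
p228,0,0
p229,0,0
p230,0,0
p231,0,0
p232,0,0
p233,0,0
p234,0,0
p235,0,0
p236,0,0
p237,0,0
p238,0,0
p239,0,0
p240,0,0
p241,0,0
p242,0,0
p243,0,0
p244,0,0
p245,0,0
p246,0,0
p247,0,0
p248,0,0
p249,0,0
p250,0,0
p251,0,0
p252,0,0
p253,0,0
p254,0,0
p255,0,0
p256,0,0
p257,0,0
p258,0,0
p259,0,0
p260,0,0
p261,0,0
p262,0,0
p263,0,0
p264,0,0
p265,0,0
p266,0,0
p267,0,0
p268,0,0
p269,0,0
p270,0,0
p271,0,0
p272,0,0
p273,0,0
p274,0,0
p275,0,0
p276,0,0
p277,0,0
p278,0,0
p279,0,0
p280,0,0
p281,0,0
p282,0,0
p283,0,0
p284,0,0
p285,0,0
p286,0,0
p287,0,0
p288,0,0
p289,0,0
p290,0,0
p291,0,0
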