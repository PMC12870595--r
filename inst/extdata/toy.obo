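format-version: 1.2

[Term]
id: SP:0000001
name: phenotypic abnormality (synthetic toy)

[Term]
id: SP:0000002
name: branch A
is_a: SP:0000001 ! phenotypic abnormality (synthetic toy)

[Term]
id: SP:0000003
name: branch B
is_a: SP:0000001

[Term]
id: SP:0000004
name: term A1
is_a: SP:0000002

[Term]
id: SP:0000005
name: term A2
is_a: SP:0000002

[Term]
id: SP:0000006
name: term B1
is_a: SP:0000003

[Term]
id: SP:0000007
name: term D (diamond under A1 and A2)
is_a: SP:0000004
is_a: SP:0000005

[Term]
id: SP:0000099
name: retired term
is_obsolete: true
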