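# ion species table, v1
# z: charge number; a: mass number; m_u: rest energy per nucleon (MeV)
# nuclear rest energies from atomic masses minus z electron masses
name	z	a	m_u	aliases
proton	1	1	938.272	p;h1;hydrogen1
deuteron	1	2	937.806	d;h2
helium4	2	4	931.845	he4;he-4;alpha
lithium7	3	7	933.405	li7;li-7
carbon12	6	12	931.244	c12;c-12;carbon
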