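# Curated human O- and N-glycan structures (IUPAC-condensed) used for
# assigning sequences to simulated abundances. Composed from standard
# O-glycan cores 1-4 and N-glycan types with common sialylation,
# fucosylation and sulfation patterns.
glycan	type
GalNAc	O
Neu5Ac(a2-6)GalNAc	O
Neu5Gc(a2-6)GalNAc	O
Neu5Ac(a2-6)[GlcNAc(b1-3)]GalNAc	O
Gal(b1-3)GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)GalNAc	O
Fuc(a1-2)Gal(b1-3)GalNAc	O
GalNAc(a1-3)[Fuc(a1-2)]Gal(b1-3)GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc	O
GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-3)GalNAc	O
GalOS(b1-3)GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)GalNAc	O
Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	O
GalNAc(b1-4)[Neu5Ac(a2-3)]Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	O
GalOS(b1-3)[Neu5Ac(a2-6)]GalNAc	O
Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
GalOS(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Gal(b1-4)GlcNAc6S(b1-6)]GalNAc	O
Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
Fuc(a1-2)Gal(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
GalOS(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(a1-3)[Fuc(a1-2)]Gal(b1-3)[GalNAc(b1-4)GlcNAc(b1-6)]GalNAc	O
GlcNAc(b1-3)GalNAc	O
Gal(b1-4)GlcNAc(b1-3)GalNAc	O
Gal(b1-3)GlcNAc(b1-3)GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)GalNAc	O
Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)GalNAc	O
Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)GalNAc	O
Neu5Ac(a2-3)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)GalNAc	O
Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)GalNAc	O
Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-3)GalNAc	O
GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)[Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-6)]GalNAc	O
Gal(b1-4)GlcNAc(b1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-6)]GalNAc	O
Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc	N
Man(a1-2)Man(a1-3)[Man(a1-2)Man(a1-6)[Man(a1-3)]Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
GlcNAc(b1-2)Man(a1-3)[GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Neu5Gc(a2-3)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)][GlcNAc(b1-4)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc	N
Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc	N
Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
GalNAc(b1-4)GlcNAc(b1-2)Man(a1-3)[GalNAc(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Neu5Ac(a2-3)Gal(b1-3)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
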