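# Curated named glycan motif library (subset of the commonly used named
# epitopes; users may supply a drop-in replacement with the same columns).
# Columns: name / pattern / constraint / excluded_context
# constraint: terminal | internal | reducing-end | flexible
# excluded_context: branch pattern that must NOT hang off the matched root
name	pattern	constraint	excluded_context
LewisX	Gal(b1-4)[Fuc(a1-3)]GlcNAc	flexible
LewisA	Gal(b1-3)[Fuc(a1-4)]GlcNAc	flexible
LewisB	Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc	flexible
LewisY	Fuc(a1-2)Gal(b1-4)[Fuc(a1-3)]GlcNAc	flexible
SialylLewisX	Neu5Ac(a2-3)Gal(b1-4)[Fuc(a1-3)]GlcNAc	flexible
SialylLewisA	Neu5Ac(a2-3)Gal(b1-3)[Fuc(a1-4)]GlcNAc	flexible
BloodGroupH	Fuc(a1-2)Gal	terminal
BloodGroupA	GalNAc(a1-3)[Fuc(a1-2)]Gal	flexible
BloodGroupB	Gal(a1-3)[Fuc(a1-2)]Gal	flexible
Tn	GalNAc	reducing-end	?(??-?)
SialylTn	Neu5Ac(a2-6)GalNAc	reducing-end	?(??-3)
Oglycan_core1	Gal(b1-3)GalNAc	reducing-end	GlcNAc(b1-6)
Oglycan_core2	Gal(b1-3)[GlcNAc(b1-6)]GalNAc	reducing-end
Oglycan_core3	GlcNAc(b1-3)GalNAc	reducing-end	GlcNAc(b1-6)
Oglycan_core4	GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc	reducing-end
SialylT	Neu5Ac(a2-3)Gal(b1-3)GalNAc	reducing-end	Neu5Ac(a2-6)
Sialyl6T	Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	reducing-end
diSialylT	Neu5Ac(a2-3)Gal(b1-3)[Neu5Ac(a2-6)]GalNAc	reducing-end
Sda	GalNAc(b1-4)[Neu5Ac(a2-3)]Gal	flexible
LacNAc_terminal	Gal(b1-4)GlcNAc	terminal
LacNAc_internal	Gal(b1-4)GlcNAc	internal
LacdiNAc	GalNAc(b1-4)GlcNAc	flexible
CoreFucose	Fuc(a1-6)GlcNAc	reducing-end
BisectingGlcNAc	GlcNAc(b1-4)Man	flexible
Oligomannose	Man(a1-2)Man	flexible
SulfatedLacNAc	Gal(b1-4)GlcNAc6S	flexible
Sialyl_a23_LacNAc	Neu5Ac(a2-3)Gal(b1-4)GlcNAc	flexible
Sialyl_a26_LacNAc	Neu5Ac(a2-6)Gal(b1-4)GlcNAc	flexible
PolyLacNAc	Gal(b1-4)GlcNAc(b1-3)Gal	flexible
SulfoSialylCore2Arm	Gal(b1-4)GlcNAc6S(b1-6)GalNAc	flexible
Neu5Gc_terminal	Neu5Gc(a2-?)	terminal
Fucose_terminal	Fuc(a1-?)	terminal
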