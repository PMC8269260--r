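isolate_id	isolate_gc	relative_name	genus	is_type_species	identity16S	ani	pocp	dddh	gc_diff
Gallibacter intestinalis	40.9	Eubacterium brachy	Eubacterium	FALSE	93.3		54.8
Gallibacter intestinalis	40.9	Eubacterium infirmum	Eubacterium	FALSE	90.7
Gallibacter intestinalis	40.9	Anaerovorax odorimutans	Anaerovorax	FALSE	90.7
Gallibacter intestinalis	40.9	Eubacterium limosum	Eubacterium	TRUE			22.5
Gallalistipes aquisgranensis	58	Alistipes onderdonkii	Alistipes	FALSE	92.5
Gallalistipes aquisgranensis	58	Alistipes finegoldii	Alistipes	FALSE	92.3
Gallalistipes aquisgranensis	58	Alistipes timonensis	Alistipes	FALSE	92.2
Gallalistipes aquisgranensis	58	Alistipes indistinctus	Alistipes	FALSE	91.6		56
Gallalistipes aquisgranensis	58	Alistipes putredinis	Alistipes	TRUE			48.1
Gemmiger gallinarum	59.2	Gemmiger formicilis	Gemmiger	TRUE	96.2	79.7	61.2	22.0
Gemmiger gallinarum	59.2	Fournierella massiliensis	Fournierella	FALSE	94.8			20.2
Gemmiger gallinarum	59.2	Subdoligranulum variabile	Subdoligranulum	FALSE	94.7	81.7		25.3
Gemmiger gallinarum	59.2	Butyricicoccus pullicaecorum	Butyricicoccus	FALSE		79.7
Olsenella gallinarum	68	Olsenella umbonata	Olsenella	FALSE	96.6
Olsenella gallinarum	68	Olsenella profusa	Olsenella	FALSE	96.2
Olsenella gallinarum	68	Olsenella uli	Olsenella	TRUE	95.8		54.9
Olsenella gallinarum	68	Olsenella scatoligenes	Olsenella	FALSE		80.4
Pseudoflavonifractor gallinarum	59.9	Pseudoflavonifractor capillosus	Pseudoflavonifractor	TRUE	98.2	82.2	56.9
Pseudoflavonifractor gallinarum	59.9	Flavonifractor plautii	Flavonifractor	FALSE	97.7
Pseudoflavonifractor gallinarum	59.9	Intestinimonas butyriciproducens	Intestinimonas	FALSE	95.3
Ructibacterium gallinarum	43.5	Acetivibrio cellulolyticus	Acetivibrio	TRUE	89.7
Ructibacterium gallinarum	43.5	Acetivibrio thermocellus	Acetivibrio	FALSE	89.6
Ructibacterium gallinarum	43.5	Acetivibrio straminisolvens	Acetivibrio	FALSE	89.4
Sellimonas monacensis	50.3	Faecalicatena contorta	Faecalicatena	TRUE	94.4		44.8
Sellimonas monacensis	50.3	Faecalicatena orotica	Faecalicatena	FALSE	93.9
Sellimonas monacensis	50.3	Coprococcus comes	Coprococcus	FALSE	93.9
Sellimonas monacensis	50.3	Ruminococcus lactaris	Ruminococcus	FALSE		78.3
Sellimonas monacensis	50.3	Dorea longicatena	Dorea	FALSE			56.4
Sellimonas monacensis	50.3	Dorea formicigenerans	Dorea	TRUE			51.7
Sellimonas monacensis	50.3	Clostridium scindens	Clostridium	FALSE			54.7
Sellimonas monacensis	50.3	Clostridium hylemonae	Clostridium	FALSE			53.1
Sellimonas monacensis	50.3	Sellimonas intestinalis	Sellimonas	TRUE	93.7		52.9
Sellimonas monacensis	50.3	Lachnoclostridium phocaeense	Lachnoclostridium	FALSE				84.6	0.3
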