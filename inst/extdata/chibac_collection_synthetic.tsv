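isolate_id	species_name	genus	family	phylum	best_hit_identity	is_syn_member
CC-01	Lactobacillus crispatus	Lactobacillus	Lactobacillaceae	Firmicutes	99.8	TRUE
CC-02	Limosilactobacillus oris	Limosilactobacillus	Lactobacillaceae	Firmicutes	99.5	TRUE
CC-03	Ligilactobacillus salivarius	Ligilactobacillus	Lactobacillaceae	Firmicutes	99.9	TRUE
CC-04	Lactobacillus gallinarum	Lactobacillus	Lactobacillaceae	Firmicutes	99.7	FALSE
CC-05	Lactobacillus helveticus	Lactobacillus	Lactobacillaceae	Firmicutes	99.4	FALSE
CC-06	Lactobacillus amylovorus	Lactobacillus	Lactobacillaceae	Firmicutes	99.6	FALSE
CC-07	Lactobacillus johnsonii	Lactobacillus	Lactobacillaceae	Firmicutes	99.9	FALSE
CC-08	Lactobacillus kitasatonis	Lactobacillus	Lactobacillaceae	Firmicutes	99.1	FALSE
CC-09	Limosilactobacillus reuteri	Limosilactobacillus	Lactobacillaceae	Firmicutes	99.8	FALSE
CC-10	Limosilactobacillus vaginalis	Limosilactobacillus	Lactobacillaceae	Firmicutes	99.3	FALSE
CC-11	Limosilactobacillus ingluviei	Limosilactobacillus	Lactobacillaceae	Firmicutes	99.2	FALSE
CC-12	Ligilactobacillus agilis	Ligilactobacillus	Lactobacillaceae	Firmicutes	99.5	FALSE
CC-13	Ligilactobacillus aviarius	Ligilactobacillus	Lactobacillaceae	Firmicutes	99.0	FALSE
CC-14	Ligilactobacillus animalis	Ligilactobacillus	Lactobacillaceae	Firmicutes	99.7	FALSE
CC-15	Enterococcus faecium	Enterococcus	Enterococcaceae	Firmicutes	100	FALSE
CC-16	Enterococcus faecalis	Enterococcus	Enterococcaceae	Firmicutes	99.9	FALSE
CC-17	Enterococcus hirae	Enterococcus	Enterococcaceae	Firmicutes	99.8	FALSE
CC-18	Enterococcus durans	Enterococcus	Enterococcaceae	Firmicutes	99.6	FALSE
CC-19	Enterococcus cecorum	Enterococcus	Enterococcaceae	Firmicutes	99.4	FALSE
CC-20	Enterococcus gallinarum	Enterococcus	Enterococcaceae	Firmicutes	99.7	FALSE
CC-21	Gemmiger gallinarum	Gemmiger	Oscillospiraceae	Firmicutes	96.2	FALSE
CC-22	Pseudoflavonifractor gallinarum	Pseudoflavonifractor	Oscillospiraceae	Firmicutes	98.2	FALSE
CC-23	Ructibacterium gallinarum	Ructibacterium	Oscillospiraceae	Firmicutes	89.7	FALSE
CC-24	Sellimonas monacensis	Sellimonas	Lachnospiraceae	Firmicutes	94.4	FALSE
CC-25	Anaerotignum lactatifermentans	Anaerotignum	Lachnospiraceae	Firmicutes	99.3	TRUE
CC-26	Gallibacter intestinalis	Gallibacter	Eubacteriaceae	Firmicutes	93.3	FALSE
CC-27	Megamonas funiformis	Megamonas	Selenomonadaceae	Firmicutes	99.5	TRUE
CC-28	Streptococcus alactolyticus	Streptococcus	Streptococcaceae	Firmicutes	99.6	FALSE
CC-29	Lactococcus lactis	Lactococcus	Streptococcaceae	Firmicutes	99.9	FALSE
CC-30	Clostridium butyricum	Clostridium	Clostridiaceae	Firmicutes	99.2	FALSE
CC-31	Erysipelatoclostridium ramosum	Erysipelatoclostridium	Erysipelotrichaceae	Firmicutes	99.0	FALSE
CC-32	Bacillus subtilis	Bacillus	Bacillaceae	Firmicutes	99.8	FALSE
CC-33	Romboutsia lituseburensis	Romboutsia	Peptostreptococcaceae	Firmicutes	98.9	FALSE
CC-34	Alistipes onderdonkii	Alistipes	Rikenellaceae	Bacteroidetes	99.6	TRUE
CC-35	Gallalistipes aquisgranensis	Gallalistipes	Rikenellaceae	Bacteroidetes	92.5	FALSE
CC-36	Phocaeicola dorei	Phocaeicola	Bacteroidaceae	Bacteroidetes	99.7	TRUE
CC-37	Bacteroides fragilis	Bacteroides	Bacteroidaceae	Bacteroidetes	99.5	FALSE
CC-38	Bifidobacterium pullorum	Bifidobacterium	Bifidobacteriaceae	Actinobacteria	99.4	TRUE
CC-39	Olsenella gallinarum	Olsenella	Atopobiaceae	Actinobacteria	96.6	FALSE
CC-40	Collinsella aerofaciens	Collinsella	Coriobacteriaceae	Actinobacteria	99.1	FALSE
CC-41	Eggerthella lenta	Eggerthella	Eggerthellaceae	Actinobacteria	99.3	FALSE
CC-42	Escherichia sp.	Escherichia	Enterobacteriaceae	Proteobacteria	99.9	TRUE
CC-43	Proteus mirabilis	Proteus	Morganellaceae	Proteobacteria	99.2	FALSE
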