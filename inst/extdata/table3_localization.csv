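gene_name,isoform,reason,previously_known,broad,narrow,focal,boundary,pan_nuclear,nucleolar,foci_outside_hc,notes
Heterochromatin protein 4,HP4-RA,ipms,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,Kc chromocenter
Heterochromatin protein 5,HP5-RA,ipms,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,Kc chromocenter
Lysine (K)-specific demethylase 4A,Kdm4A-RA,ipms,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,chromocenter in Kc and S2 and BG3
Suppressor of variegation 3-9,Su(var)3-9-RA,ipms,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,polytene chromocenter
Suppressor of variegation 3-7,Su(var)3-7-RB,literature,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,polytene chromocenter
Lethal hybrid rescue,Lhr-RA,ipms,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,broad plus centromeric foci
Heterochromatin protein 6,HP6-RA,literature,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,slight narrow HC enrichment
Oddjob,Odj-RA,ipms,FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,multiple patterns in population
Su(var)2-HP2,Su(var)2-HP2-RB,ipms,TRUE,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,narrow subdomain enriched at boundary
blanks,blanks-RA,rnai_screen,FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,tag- and cell-type-dependent patterns
CG2129,CG2129-RA,rnai_screen,FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,foci appear with expression level
FK506-binding protein 1,FK506-bp1-RA,ipms,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,interior of HP1a domain
XNP,XNP-RA,literature,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,narrow and focal in S2 cells
Suppressor of Under-Replication,SuUR-RA,literature,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,narrow subdomain within holodomain
Hormone receptor 83,Hr83-RA,rnai_screen,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,pattern depends on tag terminus
D1 chromosomal protein,D1-RA,literature,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,satellite-associated; slight narrow HC enrichment
lethal (3) neo38,l(3)neo38-RB,rnai_screen,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,focus within HP1a domain
crooked legs,crol-RD,rnai_screen,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,focus within HP1a domain
ADD domain-containing protein 1,ADD1-RB,ipms,TRUE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,focal at domain boundary; weak broad HC enrichment
proliferation disrupter,prod-RA,literature,TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,satellite-binding foci at domain edge
Hrb87F,Hrb87F-RA,rnai_screen,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,partial overlap with HP1a domain edge
Tousled-like kinase,Tlk-RF,rnai_screen,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,1-2 foci per nucleus abutting HP1a
RNA and export factor binding protein 1,Ref1-RA,ipms,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,slight HC enrichment only
sans fille,snf-RA,rnai_screen,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,nuclear except nucleolus
Hepatocyte nuclear factor 4,Hnf4-RA,rnai_screen,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,nuclear except nucleolus
bicoid-interacting protein 3,bin3-RA,rnai_screen,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,
Cullin 4,Cul4-RA,literature,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,
female lethal d,fl(2)d-RA,ipms,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,non-uniform in nucleus
jumeau,jumu-RA,rnai_screen,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,
La autoantigen-like,La-RA,ipms,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,euchromatic
Structure specific recognition protein,Ssrp-RA,rnai_screen,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,nucleolar
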