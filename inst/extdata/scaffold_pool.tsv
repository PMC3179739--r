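smiles	name	aromatic	pass_safe
c1ccccc1	benzene	TRUE	TRUE
c1ccncc1	pyridine	TRUE	TRUE
c1cncnc1	pyrimidine	TRUE	TRUE
c1cnccn1	pyrazine	TRUE	TRUE
c1ccnnc1	pyridazine	TRUE	TRUE
c1ccoc1	furan	TRUE	TRUE
c1ccsc1	thiophene	TRUE	TRUE
c1cc[nH]c1	pyrrole	TRUE	TRUE
c1c[nH]cn1	imidazole	TRUE	TRUE
c1cc[nH]n1	pyrazole	TRUE	TRUE
O1C=NC=C1	oxazole	TRUE	TRUE
O1N=CC=C1	isoxazole	TRUE	TRUE
S1C=NC=C1	thiazole	TRUE	TRUE
N1N=NC=C1	triazole	TRUE	TRUE
N1N=NN=C1	tetrazole	TRUE	TRUE
c1ccc2ccccc2c1	naphthalene	TRUE	TRUE
c1ccc2ncccc2c1	quinoline	TRUE	TRUE
c1ccc2c(c1)cc[nH]2	indole	TRUE	TRUE
c1ccc2c(c1)nc[nH]2	benzimidazole	TRUE	TRUE
c1ccc2c(c1)cco2	benzofuran	TRUE	TRUE
c1ccc2c(c1)ccs2	benzothiophene	TRUE	TRUE
c1ncc2nc[nH]c2n1	purine	TRUE	TRUE
c1ccc2c(c1)ncnc2	quinazoline	TRUE	TRUE
c1ccc2nccnc2c1	quinoxaline	TRUE	TRUE
C1C=Cc2ccccc2O1	chromene	TRUE	TRUE
c1ccc(-c2ccccc2)cc1	biphenyl	TRUE	FALSE
C(c1ccccc1)c1ccccc1	diphenylmethane	TRUE	FALSE
c1ccc(CCc2ccccc2)cc1	diphenylethane	TRUE	FALSE
C(=Cc1ccccc1)c1ccccc1	stilbene	TRUE	FALSE
O(c1ccccc1)c1ccccc1	diphenylether	TRUE	FALSE
C1c2ccccc2-c2ccccc21	fluorene	TRUE	FALSE
c1ccc2c(c1)[nH]c1ccccc12	carbazole	TRUE	FALSE
c1ccc2nc3ccccc3cc2c1	acridine	TRUE	FALSE
c1ccc2cc3ccccc3cc2c1	anthracene	TRUE	FALSE
C1CCC(CC1)c1ccccc1	cyclohexylbenzene	TRUE	FALSE
c1ccc2c(c1)CCCC2	tetralin	TRUE	FALSE
C1Cc2ccccc2C1	indane	TRUE	FALSE
c1ccc(-c2ccccn2)cc1	phenylpyridine	TRUE	FALSE
C1CCN(CC1)c1ccccc1	phenylpiperidine	TRUE	FALSE
c1ccc(Cc2ccncc2)cc1	benzylpyridine	TRUE	FALSE
C1CCCC1	cyclopentane	FALSE	TRUE
C1CCCCC1	cyclohexane	FALSE	TRUE
C1CCCCCC1	cycloheptane	FALSE	FALSE
C1CCNCC1	piperidine	FALSE	TRUE
C1CNCCN1	piperazine	FALSE	TRUE
C1COCCN1	morpholine	FALSE	TRUE
C1CCOC1	tetrahydrofuran	FALSE	TRUE
C1CCOCC1	tetrahydropyran	FALSE	TRUE
C1CCNC1	pyrrolidine	FALSE	TRUE
C1=CCCCC1	cyclohexene	FALSE	TRUE
C1CCC2CCCCC2C1	decalin	FALSE	FALSE
C1C2CC3CC1CC(C2)C3	adamantane	FALSE	FALSE
C1CCC2C(C1)CCC1C2CCC2CCCC12	gonane	FALSE	FALSE
C1CC2CCC1C2	norbornane	FALSE	FALSE
C1CCC2(C1)CCCCC2	spirodecane	FALSE	FALSE
C1COC1	oxetane	FALSE	TRUE
C1CNC1	azetidine	FALSE	TRUE
C1CSC1	thietane	FALSE	TRUE
C1CCCOCC1	oxepane	FALSE	TRUE
C1CCCNCC1	azepane	FALSE	TRUE
C1CCSC1	thiolane	FALSE	TRUE
C1COCCO1	dioxane	FALSE	TRUE
C1CSCCS1	dithiane	FALSE	TRUE
C1OCCN1	oxazolidine	FALSE	TRUE
C1CCCCCCC1	cyclooctane	FALSE	FALSE
C1CCCCCCCC1	cyclononane	FALSE	FALSE
C1CC1	cyclopropane	FALSE	TRUE
C1CCC1	cyclobutane	FALSE	TRUE
C1CCC(CC1)C1CCCCC1	bicyclohexyl	FALSE	FALSE
C1CCN(CC1)C1CCNCC1	bipiperidine	FALSE	TRUE
C1CCC(CC1)C1CCNCC1	cyclohexylpiperidine	FALSE	FALSE
C1CN(CCN1)C1CCCC1	cyclopentylpiperazine	FALSE	TRUE
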