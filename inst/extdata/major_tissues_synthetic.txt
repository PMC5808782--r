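TS:1000001	adrenal gland
TS:1000002	blood
TS:1000003	bone
TS:1000004	bone marrow
TS:1000005	nervous system
TS:1000006	eye
TS:1000007	gall bladder
TS:1000008	heart
TS:1000009	intestine
TS:1000010	kidney
TS:1000011	liver
TS:1000012	lung
TS:1000013	muscle
TS:1000014	pancreas
TS:1000015	salivary gland
TS:1000016	skin
TS:1000017	spleen
TS:1000018	stomach
TS:1000019	testis
TS:1000020	thyroid gland
TS:1000021	lymph node
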