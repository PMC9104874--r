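carrier_id	variant_id	tissue	preservation	normal_vaf	tumour_vaf	tumour_depth
PT0094	RAD51C:c.414G>C	ascites	fresh_frozen	0.50	0.75	100
PT0124	RAD51C:c.705G>T	right_ovary	fresh_frozen	0.50	0.75	100
PT0125	RAD51C:c.705G>T	left_ovary	fresh_frozen	0.50	0.95	100
PT0126	RAD51C:c.705G>T	right_ovary	fresh_frozen	0.50	0.50	100
PT0058	RAD51D:c.137C>G	alternative_tissue	fresh_frozen	0.50	0.50	100
PT0058	RAD51D:c.137C>G	right_ovary	FFPE	0.50	0.75	100
PT0145	RAD51D:c.137C>G	right_ovary	fresh_frozen	0.50	0.75	100
PT0080	RAD51D:c.620C>T	omentum	fresh_frozen	0.50	0.75	100
PT0071	RAD51D:c.620C>T	right_ovary	fresh_frozen	0.50	0.75	100
PT0071	RAD51D:c.620C>T	right_ovary	FFPE	0.50	0.75	100
PT0059	RAD51D:c.620C>T	ovary	fresh_frozen	0.50	0.95	100
PT0065	RAD51D:c.620C>T	ovary	fresh_frozen	0.50	0.50	100
PT0075	RAD51D:c.620C>T	right_ovary	fresh_frozen	0.50	0.75	100
PT0075	RAD51D:c.620C>T	right_ovary	FFPE	0.50	0.95	100
PT0076	RAD51D:c.620C>T	right_ovary	FFPE	0.50	0.95	100
PT0076	RAD51D:c.620C>T	left_ovary	FFPE	0.50	0.75	100
PT0077	RAD51D:c.620C>T	right_ovary	FFPE	0.50	0.95	100
PT0077	RAD51D:c.620C>T	left_ovary	FFPE	0.50	0.95	100
PT0074	RAD51D:c.620C>T	right_ovary	fresh_frozen	0.50	0.75	100
PT0144	RAD51D:c.620C>T	alternative_tissue	fresh_frozen	0.50	0.50	100
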