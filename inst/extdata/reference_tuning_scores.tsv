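drug	n_similar_words	precision	recall	f1	f1_ed1	f1_ed2	f1_ed3	f1_ed4
propanolol	52	0.960	0.979	0.967	0.310	0.819	0.945	0.955
glibenclamida	49	1.000	1.000	1.000	0.829	0.956	0.955	0.961
anlodipino	49	0.913	0.976	0.944	0.612	0.938	0.952	0.942
medroxiprogesterona	47	1.000	0.914	0.955	0.763	0.881	0.955	0.927
metoclopramida	46	1.000	0.977	0.989	0.750	0.977	0.965	0.964
loratadina	46	0.837	0.947	0.889	0.774	0.973	0.963	0.955
dexametasona	45	1.000	0.800	0.889	0.615	0.915	0.954	0.952
furosemida	43	0.963	1.000	0.981	0.844	1.000	0.976	0.961
prednisona	42	1.000	0.878	0.935	0.730	0.952	0.976	0.956
hidroclorotiazida	41	1.000	0.975	0.987	0.776	0.962	0.952	0.940
diclofenaco	41	0.923	0.947	0.935	0.812	0.914	0.950	0.912
ciprofloxacino	37	1.000	0.918	0.958	0.520	0.878	0.935	0.922
espironolactona	36	1.000	1.000	1.000	0.714	0.941	0.948	0.962
salbutamol	36	1.000	0.972	0.986	0.819	0.956	0.976	0.943
clonazepam	34	1.000	1.000	1.000	0.692	0.969	0.961	0.939
beclometasona	33	1.000	0.967	0.984	0.777	0.935	0.961	0.921
dexclorfeniramina	31	1.000	0.903	0.949	0.708	0.872	0.960	0.959
metronidazol	30	0.965	0.965	0.965	0.816	0.964	0.942	0.926
prednisolona	30	0.965	0.965	0.965	0.739	0.925	0.976	0.966
isossorbida	29	0.963	1.000	0.981	0.761	0.960	0.957	0.936
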