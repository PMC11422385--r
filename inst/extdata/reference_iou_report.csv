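class_name,iou_train,iou_val,score,consistent
Optic cup,0.944777,0.668727,0.779147,TRUE
Optic disk,0.988255,0.847226,0.903637,TRUE
Retinal vessel,0.979049,0.847226,0.903637,FALSE
Macular,0.911657,0.340241,0.568807,TRUE
Hemorrhage,0.581202,0.298246,0.411429,TRUE
Cotton-wool spot,0.523801,0.260054,0.365553,TRUE
Drusen,0.453724,0.212842,0.309194,TRUE
Atrophic arc,0.423962,0.362179,0.386892,TRUE
Choroidal atrophy,0.490633,0.280601,0.364614,TRUE
Choroidal neovascularization,0.477546,0.318491,0.382113,TRUE
Exudation,0.697246,0.420536,0.531220,TRUE
Macular degeneration,0.537707,0.085275,0.266248,TRUE
Geographic atrophy,0.99302,0.350863,0.607726,TRUE
Retinal nerve fiber layer defects,0.960778,0.651179,0.775019,TRUE
Retinal defect,0.451425,0.129582,0.258319,TRUE
Sclera exposure,0.467256,0.197711,0.305529,TRUE
Tessellation,0.494761,0.37732,0.424297,TRUE
Neovessels elsewhere,0.996863,0.333022,0.598558,TRUE
Vitreous hemorrhage,0.604791,0.29893,0.421275,TRUE
Retinal detachment,0.964422,0.381874,0.614893,TRUE
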