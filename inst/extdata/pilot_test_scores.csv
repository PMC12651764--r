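"sample","criterion","true","predicted"
1,"clearance_buccal",0.5,0
2,"clearance_buccal",0,0
3,"clearance_buccal",0,0
4,"clearance_buccal",0,0
5,"clearance_buccal",0,0
6,"clearance_buccal",0,0
7,"clearance_buccal",0,0
8,"clearance_buccal",0,0.3
9,"clearance_buccal",0,0
10,"clearance_buccal",0,0
1,"clearance_lingual",0,0
2,"clearance_lingual",0,0
3,"clearance_lingual",0,0
4,"clearance_lingual",1,0
5,"clearance_lingual",2,0
6,"clearance_lingual",0,0
7,"clearance_lingual",0,2
8,"clearance_lingual",1,0.4
9,"clearance_lingual",0,0
10,"clearance_lingual",0,2
1,"clearance_gingival",0,0
2,"clearance_gingival",0,0.6
3,"clearance_gingival",0,0
4,"clearance_gingival",0,0
5,"clearance_gingival",0,0
6,"clearance_gingival",0,1
7,"clearance_gingival",0,0
8,"clearance_gingival",0,0.3
9,"clearance_gingival",1,0
10,"clearance_gingival",1,0
1,"preservation_between",2,2
2,"preservation_between",2,2
3,"preservation_between",1,2
4,"preservation_between",2,2
5,"preservation_between",0,2
6,"preservation_between",1,2
7,"preservation_between",2,2
8,"preservation_between",1,2
9,"preservation_between",2,2
10,"preservation_between",2,2
1,"occlusal_preservation",1,1
2,"occlusal_preservation",1,1
3,"occlusal_preservation",1,1
4,"occlusal_preservation",1,1
5,"occlusal_preservation",0.5,1
6,"occlusal_preservation",0,1
7,"occlusal_preservation",1,1
8,"occlusal_preservation",0,1
9,"occlusal_preservation",1,1
10,"occlusal_preservation",2,1
1,"caries_removal",7,8.5
2,"caries_removal",8,9
3,"caries_removal",7,4.7
4,"caries_removal",7,6
5,"caries_removal",8,7.4
6,"caries_removal",8,3.2
7,"caries_removal",9,8.8
8,"caries_removal",6,2.2
9,"caries_removal",4,5.4
10,"caries_removal",8,8.1
1,"no_undermined_enamel",1,0
2,"no_undermined_enamel",0,0
3,"no_undermined_enamel",0,0
4,"no_undermined_enamel",0,0
5,"no_undermined_enamel",0,0
6,"no_undermined_enamel",0,1.28
7,"no_undermined_enamel",2,1.9
8,"no_undermined_enamel",0,0
9,"no_undermined_enamel",1,0
10,"no_undermined_enamel",0,0
1,"adjacent_damage",0,0
2,"adjacent_damage",0,0
3,"adjacent_damage",0,0
4,"adjacent_damage",-2,0
5,"adjacent_damage",-1,0
6,"adjacent_damage",-1,0
7,"adjacent_damage",0,0
8,"adjacent_damage",0,0
9,"adjacent_damage",0,0
10,"adjacent_damage",-1,0
1,"total",11.5,11.5
2,"total",11,12.6
3,"total",9,7.7
4,"total",9,9
5,"total",9.5,10.4
6,"total",8,8.5
7,"total",12,13.8
8,"total",8,6.3
9,"total",9,8.4
10,"total",12,13.1
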