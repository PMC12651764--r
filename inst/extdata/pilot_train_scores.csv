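"sample","criterion","true","predicted"
1,"clearance_buccal",1,1
2,"clearance_buccal",0,0
3,"clearance_buccal",0,0.2
4,"clearance_buccal",0,0.4
5,"clearance_buccal",1,1.3
6,"clearance_buccal",0,0.5
7,"clearance_buccal",1,0.7
8,"clearance_buccal",2,1.4
9,"clearance_buccal",0,0
10,"clearance_buccal",1,0.8
11,"clearance_buccal",2,1
12,"clearance_buccal",1,1.1
13,"clearance_buccal",2,1.3
14,"clearance_buccal",1,0.2
15,"clearance_buccal",0,0.4
16,"clearance_buccal",0,0.2
17,"clearance_buccal",1,0.9
18,"clearance_buccal",1,1
19,"clearance_buccal",0,0.1
20,"clearance_buccal",1,0.7
1,"clearance_lingual",2,1.2
2,"clearance_lingual",2,1.6
3,"clearance_lingual",2,1.8
4,"clearance_lingual",2,1.7
5,"clearance_lingual",0,0.3
6,"clearance_lingual",2,1.3
7,"clearance_lingual",2,1.9
8,"clearance_lingual",2,1.9
9,"clearance_lingual",1,0.5
10,"clearance_lingual",0,0.1
11,"clearance_lingual",0,0.1
12,"clearance_lingual",0,0
13,"clearance_lingual",2,1.1
14,"clearance_lingual",2,1.9
15,"clearance_lingual",2,1.9
16,"clearance_lingual",0,0.3
17,"clearance_lingual",1,0.7
18,"clearance_lingual",0,0
19,"clearance_lingual",1,1
20,"clearance_lingual",0,0
1,"clearance_gingival",2,1.5
2,"clearance_gingival",1,0.3
3,"clearance_gingival",2,1.8
4,"clearance_gingival",2,1.2
5,"clearance_gingival",2,1.9
6,"clearance_gingival",2,1.1
7,"clearance_gingival",2,1.9
8,"clearance_gingival",2,1.9
9,"clearance_gingival",0,0.1
10,"clearance_gingival",2,1.5
11,"clearance_gingival",0,0.8
12,"clearance_gingival",2,1.9
13,"clearance_gingival",2,1.7
14,"clearance_gingival",0,0.7
15,"clearance_gingival",2,1.9
16,"clearance_gingival",0,0.5
17,"clearance_gingival",1,1.6
18,"clearance_gingival",1,0.7
19,"clearance_gingival",0,0.1
20,"clearance_gingival",0,0.2
1,"preservation_between",2,1.8
2,"preservation_between",2,1.8
3,"preservation_between",2,1.9
4,"preservation_between",2,1.9
5,"preservation_between",1,1.4
6,"preservation_between",2,1.8
7,"preservation_between",2,1.9
8,"preservation_between",2,1.9
9,"preservation_between",2,1.9
10,"preservation_between",2,1.9
11,"preservation_between",2,1.7
12,"preservation_between",2,1.7
13,"preservation_between",2,1.8
14,"preservation_between",2,1.9
15,"preservation_between",2,1.9
16,"preservation_between",2,1.8
17,"preservation_between",2,1.8
18,"preservation_between",2,1.9
19,"preservation_between",2,1.9
20,"preservation_between",1,1.7
1,"occlusal_preservation",1,0.9
2,"occlusal_preservation",1,0.9
3,"occlusal_preservation",1,0.9
4,"occlusal_preservation",1,0.9
5,"occlusal_preservation",1,0.9
6,"occlusal_preservation",1,0.9
7,"occlusal_preservation",1,0.9
8,"occlusal_preservation",1,0.9
9,"occlusal_preservation",1,0.9
10,"occlusal_preservation",1,0.9
11,"occlusal_preservation",1,0.9
12,"occlusal_preservation",1,0.9
13,"occlusal_preservation",1,0.9
14,"occlusal_preservation",1,0.9
15,"occlusal_preservation",1,0.9
16,"occlusal_preservation",1,0.9
17,"occlusal_preservation",1,0.9
18,"occlusal_preservation",1,0.9
19,"occlusal_preservation",1,0.9
20,"occlusal_preservation",1,0.9
1,"caries_removal",8,8.1
2,"caries_removal",9,8.6
3,"caries_removal",9,8.9
4,"caries_removal",9,8.7
5,"caries_removal",9,8.5
6,"caries_removal",7,8.3
7,"caries_removal",9,8.9
8,"caries_removal",9,8.9
9,"caries_removal",9,8.9
10,"caries_removal",9,8.9
11,"caries_removal",9,8
12,"caries_removal",9,8.8
13,"caries_removal",7,7.3
14,"caries_removal",9,8.7
15,"caries_removal",9,8.9
16,"caries_removal",9,8.7
17,"caries_removal",9,8.5
18,"caries_removal",9,8.7
19,"caries_removal",7,7.1
20,"caries_removal",7,7.2
1,"no_undermined_enamel",2,1.7
2,"no_undermined_enamel",1,0.9
3,"no_undermined_enamel",2,1.8
4,"no_undermined_enamel",2,1.8
5,"no_undermined_enamel",2,1.6
6,"no_undermined_enamel",2,1.4
7,"no_undermined_enamel",2,1.9
8,"no_undermined_enamel",2,1.9
9,"no_undermined_enamel",0,0
10,"no_undermined_enamel",1,0.4
11,"no_undermined_enamel",0,0.3
12,"no_undermined_enamel",1,0.6
13,"no_undermined_enamel",1,0.9
14,"no_undermined_enamel",2,1.8
15,"no_undermined_enamel",2,1.9
16,"no_undermined_enamel",0,0.1
17,"no_undermined_enamel",2,1.6
18,"no_undermined_enamel",0,0
19,"no_undermined_enamel",0,0
20,"no_undermined_enamel",0,0
1,"adjacent_damage",0,0
2,"adjacent_damage",0,0
3,"adjacent_damage",0,0
4,"adjacent_damage",0,0
5,"adjacent_damage",0,0
6,"adjacent_damage",0,0
7,"adjacent_damage",0,0
8,"adjacent_damage",0,0
9,"adjacent_damage",0,0
10,"adjacent_damage",0,0
11,"adjacent_damage",0,0
12,"adjacent_damage",0,0
13,"adjacent_damage",0,0
14,"adjacent_damage",0,0
15,"adjacent_damage",0,0
16,"adjacent_damage",0,0
17,"adjacent_damage",0,0
18,"adjacent_damage",0,0
19,"adjacent_damage",0,0
20,"adjacent_damage",0,0
1,"total",18,16.6
2,"total",16,14.6
3,"total",18,17.7
4,"total",18,17
5,"total",16,16.3
6,"total",16,15.6
7,"total",19,18.7
8,"total",20,19.4
9,"total",13,12.7
10,"total",16,14.8
11,"total",14,13.2
12,"total",16,15
13,"total",17,15.3
14,"total",17,16.3
15,"total",18,18.4
16,"total",12,12.9
17,"total",17,16.5
18,"total",14,13.5
19,"total",11,11.4
20,"total",10,11.19
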