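{"package":"lpxevo","version":"0.1.0","seed":1,"settings":{"seed":1,"cutoff":0.01,"avg_query_len":320,"genome_size":20000,"hmm_n_trials":20000,"bootstrap_reps":200,"min_support":70,"max_gap":3,"hmm_occupancy":0.5,"hmm_calibration_n":800,"outgroup":null},"sim":{"n_taxa":20,"seed":1,"tree_height":0.75,"families":["lpxA","lpxC","lpxD","lpxH","lpxB","lpxK","waaA","lpxL","lpxM","fabZ"],"dup_rate":0.05,"loss_rate":0.05,"subs_model":"wag","root_len":300,"motif_family":"lpxH","fusion_pair":["lpxC","fabZ"],"fusion_prob":0.2,"n_decoys":15},"stages":{"simulate":{"genomes":20,"genes":523,"families":10},"search":{"ref_genome":"G05","assignments":223,"eff_db_len":6400000},"hmm":{"models":10,"hits":227},"classify":{"assignments":227,"motif_calls":30},"trees":{"gene_trees":10,"bootstrap_reps":200},"events":{"families_with_gain":10},"context":{"clusters":36,"fusions":4},"report":{"genomes":20}},"artifacts":{"assignments.tsv":"2aa4b0e9346751aba0fb98c86d44ec5d","cluster_conservation.tsv":"2fe655d7420b066b60e0d4ac5a93a8ed","clusters.tsv":"1e8ad4218ebdaa478386fbb2b486eb4d","distribution.tsv":"e696e65fe6f5e746b788e9301127a0f4","distribution.txt":"dde5fd6ecaff3ec8e98373e340356e05","events.json":"de1b191956c0d9f7f83a954433453557","fusions.tsv":"a758cd36ce2e7da47c08228927a674e4","gene_table.tsv":"916d30928d030acc16c0ccf2f0908172","gene_trees/fabZ.nwk":"1fadfa5d4c01be9fe4f27a6908298c9b","gene_trees/lpxA.nwk":"35ce4e479a9ac526d8d0a092037974c5","gene_trees/lpxB.nwk":"d7713f21b7b267370766e95b22098f6e","gene_trees/lpxC.nwk":"5e1d48997b0e67335f04cd4d5cb67543","gene_trees/lpxD.nwk":"2c10ede737fe780e4da7dca29bc9d08a","gene_trees/lpxH.nwk":"ec4d4d30aa9ddae3c585753a66f0020f","gene_trees/lpxK.nwk":"5262bba22a028a566bd4ff7d218b3d1d","gene_trees/lpxL.nwk":"87445444109959ad23c6dc6758cb3830","gene_trees/lpxM.nwk":"59712a53afe26072c0df1061b4d0a7c3","gene_trees/waaA.nwk":"6b3c1ac8ae6468533f6086b11e4eb5ae","hmm_hits.tsv":"25e56fb7e3159120067055b0bf3ce10c","hmms/fabZ.json":"6dc147d5a9aff8144ba0e9ceb504a98c","hmms/lpxA.json":"f7da6ae928eae83b07ec5768fa282a5b","hmms/lpxB.json":"eb3d5c2f2c11178fc997b824892de9f8","hmms/lpxC.json":"93f099acc28420c0f2c3c5796d1dd59d","hmms/lpxD.json":"d0a52ab39d8fa89d272b9523d4c263c1","hmms/lpxH.json":"f33ff724e208947edd94334cc2d0617e","hmms/lpxK.json":"33aa300bc297d04feb12603bab0a39d6","hmms/lpxL.json":"97697463dd7d37f8bf55a7c401efa4bd","hmms/lpxM.json":"b42db4bb74df2f547e723783e3752e0c","hmms/waaA.json":"b66520cbbb1567c8332e71d2fb93f24e","motif_calls.tsv":"3779bc29327079de8bfbc09b6c7a4b7a","presence_matrix.tsv":"33d1f3ee5506dd696cc61d7981cc34c6","proteomes/G01.faa":"2917b85f6ad2793e07b00eac1642fd3d","proteomes/G02.faa":"40f5410ddc604dac7528a7c90d460266","proteomes/G03.faa":"971d4718057637c3be91c6c0be5c111d","proteomes/G04.faa":"0ad8d04a5a69b2f3718a178456ddfaba","proteomes/G05.faa":"d0736e4422b182a2cdccad197c066d0f","proteomes/G06.faa":"cf49bd9020c5e67349071fe71fbab2b5","proteomes/G07.faa":"9bee6c3228418865a02e26d63f669bd8","proteomes/G08.faa":"352159ef77300e17d4a043556769245a","proteomes/G09.faa":"22eda60de66fa32aec2128f7ca7f1168","proteomes/G10.faa":"1fc510adba790c0a5bb549aa448090ec","proteomes/G11.faa":"65036faedcbc024f0911523825cc5b37","proteomes/G12.faa":"579261184b68e79e131e6b5278dd1e1c","proteomes/G13.faa":"baa0228acf8f598322d2a5c217ddc404","proteomes/G14.faa":"ba8e2fcdc6956d3dc3dd5d0a7db96e24","proteomes/G15.faa":"5499bb70ca6a2dff28ee5f5ba94d2ad3","proteomes/G16.faa":"00447e15d6993547b73bde374fc121d9","proteomes/G17.faa":"5d430d2ccb412dd4eef9af29bf2e493b","proteomes/G18.faa":"cedd23116ab40205365b0e6fc0c16aac","proteomes/G19.faa":"ef064e1661a80118a3bf7a05e4ec0aea","proteomes/G20.faa":"2771f75ed9e306305d7f3a0d8afcb0d6","rbh.tsv":"988fcbb31ea35c3f80489458efee4d75","species_tree.nwk":"6509012872ab4a651a31a12ecd75ae1e","truth.json":"faca2c6ceae7b7056218f08f7b0a2240"}}
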