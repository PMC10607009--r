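# Pheromone-trap catches at Isahaya, May 2021.  Collection was daily or
# at 2- to 5-day intervals: a row covers the interval_days days ending on
# collection_date.  The printed table only shows counts on collection
# dates; interval lengths here are reconstructed from the blank runs.
# SYNTHETIC/INFERRED: the 2021-06-01 row is not printed in the source
# table; a positive catch covering 31 May is implied by the published
# 31 May fail mark and the published 3-day hitting ratio (8/18 = 0.44),
# so a minimal count of 1 over a 2-day interval is assumed here.
site,collection_date,count,interval_days
Isahaya,2021-05-01,0,1
Isahaya,2021-05-05,0,4
Isahaya,2021-05-07,0,2
Isahaya,2021-05-12,0,5
Isahaya,2021-05-17,7,5
Isahaya,2021-05-18,0,1
Isahaya,2021-05-19,0,1
Isahaya,2021-05-20,2,1
Isahaya,2021-05-21,19,1
Isahaya,2021-05-22,3,1
Isahaya,2021-05-23,2,1
Isahaya,2021-05-24,3,1
Isahaya,2021-05-25,7,1
Isahaya,2021-05-27,2,2
Isahaya,2021-05-28,0,1
Isahaya,2021-05-29,3,1
Isahaya,2021-05-30,0,1
Isahaya,2021-06-01,1,2
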