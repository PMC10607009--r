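# Published per-day evaluation marks for Isahaya, May 2021.
site,date,mark_3day,mark_5day
Isahaya,2021-05-01,F,F
Isahaya,2021-05-02,-,-
Isahaya,2021-05-03,-,-
Isahaya,2021-05-04,F,F
Isahaya,2021-05-05,-,-
Isahaya,2021-05-06,F,F
Isahaya,2021-05-07,F,F
Isahaya,2021-05-08,F,F
Isahaya,2021-05-09,F,F
Isahaya,2021-05-10,F,F
Isahaya,2021-05-11,-,-
Isahaya,2021-05-12,F,H
Isahaya,2021-05-13,F,H
Isahaya,2021-05-14,H,H
Isahaya,2021-05-15,H,H
Isahaya,2021-05-16,H,H
Isahaya,2021-05-17,-,-
Isahaya,2021-05-18,-,-
Isahaya,2021-05-19,H,H
Isahaya,2021-05-20,H,H
Isahaya,2021-05-21,-,-
Isahaya,2021-05-22,-,-
Isahaya,2021-05-23,H,H
Isahaya,2021-05-24,-,-
Isahaya,2021-05-25,-,-
Isahaya,2021-05-26,H,H
Isahaya,2021-05-27,-,-
Isahaya,2021-05-28,H,H
Isahaya,2021-05-29,-,-
Isahaya,2021-05-30,-,-
Isahaya,2021-05-31,F,-
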