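# Published per-day evaluation marks for Koshi, May 2021.
# H = hit, F = fail, - = excluded negative day, blank = not shown.
site,date,mark_3day,mark_5day
Koshi,2021-05-01,H,H
Koshi,2021-05-02,-,-
Koshi,2021-05-03,-,-
Koshi,2021-05-04,H,H
Koshi,2021-05-05,-,-
Koshi,2021-05-06,H,H
Koshi,2021-05-07,H,H
Koshi,2021-05-08,H,H
Koshi,2021-05-09,H,H
Koshi,2021-05-10,H,H
Koshi,2021-05-11,-,-
Koshi,2021-05-12,H,H
Koshi,2021-05-13,H,H
Koshi,2021-05-14,F,H
Koshi,2021-05-15,F,H
Koshi,2021-05-16,H,H
Koshi,2021-05-17,-,-
Koshi,2021-05-18,-,-
Koshi,2021-05-19,H,H
Koshi,2021-05-20,H,H
Koshi,2021-05-21,-,-
Koshi,2021-05-22,-,-
Koshi,2021-05-23,H,H
Koshi,2021-05-24,-,-
Koshi,2021-05-25,-,-
Koshi,2021-05-26,F,F
Koshi,2021-05-27,-,-
Koshi,2021-05-28,H,H
Koshi,2021-05-29,-,-
Koshi,2021-05-30,-,-
Koshi,2021-05-31,F,-
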