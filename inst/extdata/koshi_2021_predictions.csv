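# Daily migration predictions for the Koshi trap, May 2021.
# predicted: Yes/No; source: take-off province of the earliest arrival
# (ZJ Zhejiang, FJ Fujian, GD Guangdong, JX Jiangxi, TW Taiwan);
# ft_h: flight time in whole hours from the 10:00 UTC take-off of the
# previous evening.
site,date,predicted,source,ft_h
Koshi,2021-05-01,Yes,ZJ,12
Koshi,2021-05-02,No,,
Koshi,2021-05-03,No,,
Koshi,2021-05-04,Yes,JX,38
Koshi,2021-05-05,No,,
Koshi,2021-05-06,Yes,TW,35
Koshi,2021-05-07,Yes,ZJ,29
Koshi,2021-05-08,Yes,ZJ,23
Koshi,2021-05-09,Yes,ZJ,37
Koshi,2021-05-10,Yes,FJ,36
Koshi,2021-05-11,No,,
Koshi,2021-05-12,Yes,JX,35
Koshi,2021-05-13,Yes,FJ,29
Koshi,2021-05-14,Yes,FJ,32
Koshi,2021-05-15,Yes,ZJ,20
Koshi,2021-05-16,Yes,TW,20
Koshi,2021-05-17,No,,
Koshi,2021-05-18,No,,
Koshi,2021-05-19,Yes,ZJ,30
Koshi,2021-05-20,Yes,TW,20
Koshi,2021-05-21,No,,
Koshi,2021-05-22,No,,
Koshi,2021-05-23,Yes,TW,36
Koshi,2021-05-24,No,,
Koshi,2021-05-25,No,,
Koshi,2021-05-26,Yes,ZJ,11
Koshi,2021-05-27,No,,
Koshi,2021-05-28,Yes,ZJ,23
Koshi,2021-05-29,No,,
Koshi,2021-05-30,No,,
Koshi,2021-05-31,No,,
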