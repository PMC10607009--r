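# Daily migration predictions for the Isahaya trap, May 2021.
# Columns as in koshi_2021_predictions.csv.
site,date,predicted,source,ft_h
Isahaya,2021-05-01,Yes,ZJ,11
Isahaya,2021-05-02,No,,
Isahaya,2021-05-03,No,,
Isahaya,2021-05-04,Yes,GD,35
Isahaya,2021-05-05,No,,
Isahaya,2021-05-06,Yes,TW,33
Isahaya,2021-05-07,Yes,ZJ,24
Isahaya,2021-05-08,Yes,ZJ,21
Isahaya,2021-05-09,Yes,ZJ,32
Isahaya,2021-05-10,Yes,FJ,34
Isahaya,2021-05-11,No,,
Isahaya,2021-05-12,Yes,ZJ,26
Isahaya,2021-05-13,Yes,FJ,27
Isahaya,2021-05-14,Yes,FJ,29
Isahaya,2021-05-15,Yes,ZJ,17
Isahaya,2021-05-16,Yes,TW,18
Isahaya,2021-05-17,No,,
Isahaya,2021-05-18,No,,
Isahaya,2021-05-19,Yes,FJ,31
Isahaya,2021-05-20,Yes,GD,32
Isahaya,2021-05-21,No,,
Isahaya,2021-05-22,No,,
Isahaya,2021-05-23,Yes,ZJ,36
Isahaya,2021-05-24,No,,
Isahaya,2021-05-25,No,,
Isahaya,2021-05-26,Yes,TW,30
Isahaya,2021-05-27,No,,
Isahaya,2021-05-28,Yes,ZJ,20
Isahaya,2021-05-29,No,,
Isahaya,2021-05-30,No,,
Isahaya,2021-05-31,No,,
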