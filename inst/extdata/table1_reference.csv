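"record_id","patient_id","excision_date","histopath_date","diagnosis","morphology","body_site"
"HP01","TP01","2017-11-13","2017-11-16","C43","55320002","Entire skin of abdomen"
"HP02","TP02","2017-12-20","2017-12-24","C43","55320002","Entire skin of abdomen"
"HP03","TP03","2018-02-07","2018-02-17","D03","77986002","Entire skin of abdomen"
"HP04","TP04","2018-02-08","2018-07-13","C43","2092003","Entire skin of chest"
"HP05","TP05","2018-02-24","2018-03-03","C43","2092003","Entire skin of back"
"HP06","TP06","2018-03-22","2018-04-01","C43","55320002","Entire skin of back"
"HP07","TP07","2018-06-30","2018-07-13","D03","77986002","Entire skin of back"
"HP08","TP08","2018-05-25","2018-07-16","C43","55320002","Entire skin of back"
"HP09","TP09","2018-06-01","2018-07-04","C43","2092003","Entire skin of back"
"HP10","TP10","2018-06-27","2018-07-07","D03","61217001","Entire skin of back"
"HP11","TP11","2018-09-13","2018-11-24","D03","77986002","Entire skin of back"
"HP12","TP12","2018-08-10","2018-08-29","C43","2092003","Skin tissue"
"HP13","TP13","2018-09-22","2018-10-01","D03","77986002","Entire skin of shoulder"
"HP14","TP14","2018-10-09","2018-10-12","C43","55320002","Entire skin of cheek"
"HP15","TP15","2018-11-13","2018-11-20","C43","2092003","Entire skin of cheek"
"HP15B","TP15","2019-01-02","2019-01-09","C43","2092003","Entire skin of cheek"
"HP16","TP16","2018-11-27","2018-12-04","C43","55320002","Entire skin of chin"
"HP17","TP17","2018-12-23","2018-12-30","C43","55320002","Entire skin of head"
"HP18","TP18","2019-02-27","2019-03-07","C43","55320002","Entire skin of foot"
"HP19","TP19","2019-02-08","2019-02-23","C43","2092003","Entire skin of lower leg"
"HP20","TP20","2019-03-10","2019-03-28","D03","77986002","Entire skin of forearm"
"HP21","TP21","2019-05-10","2019-05-18","C43","44474009","Entire skin of upper extremity"
"HP22","TP22","2020-07-27","2020-08-03","C43","55320002","Entire skin of upper arm"
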