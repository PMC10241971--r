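"case_id","patient_id","exam_date","diagnosis","plan","region","image_valid"
"TD01","TP01","2017-11-06","C43","EXCISION","TORSO_FRONT","TRUE"
"TD02","TP02","2017-12-01","D22","EXCISION","TORSO_FRONT","TRUE"
"TD03","TP03","2017-12-26","D48.5","EXCISION","TORSO_FRONT","TRUE"
"TD04","TP04","2018-01-20","D48.5","EXCISION","TORSO_FRONT","TRUE"
"TD05","TP05","2018-02-14","C43","EXCISION","TORSO_BACK","TRUE"
"TD06","TP06","2018-03-11","C43","EXCISION","TORSO_BACK","TRUE"
"TD07","TP07","2018-04-05","D22","CHECKUP_12M","TORSO_BACK","TRUE"
"TD08","TP08","2018-04-30","D48.5","EXCISION","TORSO_BACK","TRUE"
"TD09","TP09","2018-05-25","D48.5","EXCISION","TORSO_BACK","TRUE"
"TD10","TP10","2018-06-19","D48.5","EXCISION","TORSO_BACK","TRUE"
"TD11","TP11","2018-07-14","D48.5","EXCISION","TORSO_BACK","TRUE"
"TD12","TP12","2018-08-08","C43","EXCISION","TORSO_BACK","TRUE"
"TD13","TP13","2018-09-02","D48.5","EXCISION","RIGHT_ARM_LEFT_SIDE","TRUE"
"TD14","TP14","2018-09-27","D48.5","EXCISION","HEAD_NECK_FRONT","TRUE"
"TD15","TP15","2018-10-22","D48.5","EXCISION","HEAD_NECK_FRONT","TRUE"
"TD16","TP16","2018-11-16","D48.5","EXCISION","HEAD_NECK_FRONT","TRUE"
"TD17","TP17","2018-12-11","C43","EXCISION","HEAD_NECK_BACK","TRUE"
"TD18","TP18","2019-01-05","D48.5","EXCISION","LEFT_LEG_FRONT","TRUE"
"TD19","TP19","2019-01-30","D48.5","EXCISION","LEFT_LEG_FRONT","TRUE"
"TD20","TP20","2019-02-24","D48.5","VISIT_DERMATOLOGIST","LEFT_ARM_BACK","TRUE"
"TD21","TP21","2019-03-21","D48.5","EXCISION","LEFT_ARM_BACK","TRUE"
"TD22","TP22","2019-04-15","D48.5","EXCISION","LEFT_ARM_UP","TRUE"
"TD02B","TP02","2017-11-14","D03","EXCISION","TORSO_SIDES","TRUE"
"TD07B","TP07","2018-03-15","D22","CHECKUP_6M","TORSO_SIDES","TRUE"
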