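"subject_id","video_id","label","clip","landmarks"
"S01","S01_neutral","neutral",1,"clip_01_landmarks.csv"
"S01","S01_neutral","neutral",2,"clip_02_landmarks.csv"
"S01","S01_low","low",3,"clip_03_landmarks.csv"
"S01","S01_low","low",4,"clip_04_landmarks.csv"
"S01","S01_high","high",5,"clip_05_landmarks.csv"
"S01","S01_high","high",6,"clip_06_landmarks.csv"
"S02","S02_neutral","neutral",7,"clip_07_landmarks.csv"
"S02","S02_neutral","neutral",8,"clip_08_landmarks.csv"
"S02","S02_low","low",9,"clip_09_landmarks.csv"
"S02","S02_low","low",10,"clip_10_landmarks.csv"
"S02","S02_high","high",11,"clip_11_landmarks.csv"
"S02","S02_high","high",12,"clip_12_landmarks.csv"
"S03","S03_neutral","neutral",13,"clip_13_landmarks.csv"
"S03","S03_neutral","neutral",14,"clip_14_landmarks.csv"
"S03","S03_low","low",15,"clip_15_landmarks.csv"
"S03","S03_low","low",16,"clip_16_landmarks.csv"
"S03","S03_high","high",17,"clip_17_landmarks.csv"
"S03","S03_high","high",18,"clip_18_landmarks.csv"
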