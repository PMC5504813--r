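name,age,sex,zipcode,disease
Mary,37,F,22071,Pneumonia
Alice,35,F,22098,Diabetes
Betsy,36,F,23061,Anemia
David,61,M,55107,Pneumonia
Tom,63,M,55099,Diabetes
James,66,M,55324,Diabetes
Eric,62,M,55229,Pneumonia
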