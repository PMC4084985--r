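year,zone,count
2007,1,11
2007,2,505
2007,3,622
2007,4,662
2007,5,15
2007,6,28
2007,7,883
2008,1,0
2008,2,304
2008,3,448
2008,4,321
2008,5,1
2008,6,4
2008,7,289
2009,1,0
2009,2,267
2009,3,432
2009,4,123
2009,5,8
2009,6,1
2009,7,419
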