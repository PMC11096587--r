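year,sex,age_band,value
2006,M,25-34,15.6
2006,M,35-44,12.7
2006,M,45-54,9.6
2006,M,55-64,5.8
2006,M,65-74,3.2
2006,M,75+,1.7
2006,W,25-34,15.5
2006,W,35-44,13.0
2006,W,45-54,10.1
2006,W,55-64,6.5
2006,W,65-74,3.9
2006,W,75+,2.6
2020,M,25-34,17.6
2020,M,35-44,15.9
2020,M,45-54,12.6
2020,M,55-64,9.6
2020,M,65-74,5.7
2020,M,75+,3.2
2020,W,25-34,17.1
2020,W,35-44,16.7
2020,W,45-54,13.6
2020,W,55-64,10.9
2020,W,65-74,7.0
2020,W,75+,4.8
2036,M,25-34,15.0
2036,M,35-44,16.6
2036,M,45-54,16.0
2036,M,55-64,13.0
2036,M,65-74,9.2
2036,M,75+,6.4
2036,W,25-34,14.6
2036,W,35-44,16.7
2036,W,45-54,16.9
2036,W,55-64,14.5
2036,W,65-74,11.1
2036,W,75+,9.7
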