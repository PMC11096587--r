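year,sex,age_band,factor,value
2006,M,25-34,t2d,1.3
2006,M,35-44,t2d,2.6
2006,M,45-54,t2d,7.0
2006,M,55-64,t2d,12.6
2006,M,65-74,t2d,16.9
2006,M,75+,t2d,18.3
2006,W,25-34,t2d,1.0
2006,W,35-44,t2d,2.4
2006,W,45-54,t2d,5.9
2006,W,55-64,t2d,13.5
2006,W,65-74,t2d,18.4
2006,W,75+,t2d,17.7
2006,M,25-34,obesity,12.2
2006,M,35-44,obesity,15.5
2006,M,45-54,obesity,17.3
2006,M,55-64,obesity,16.1
2006,M,65-74,obesity,13.2
2006,M,75+,obesity,8.9
2006,W,25-34,obesity,7.1
2006,W,35-44,obesity,10.5
2006,W,45-54,obesity,14.8
2006,W,55-64,obesity,19.0
2006,W,65-74,obesity,19.0
2006,W,75+,obesity,18.3
2006,M,25-34,smoking,16.7
2006,M,35-44,smoking,17.5
2006,M,45-54,smoking,22.6
2006,M,55-64,smoking,18.5
2006,M,65-74,smoking,13.8
2006,M,75+,smoking,8.3
2006,W,25-34,smoking,8.4
2006,W,35-44,smoking,12.4
2006,W,45-54,smoking,17.6
2006,W,55-64,smoking,11.3
2006,W,65-74,smoking,7.8
2006,W,75+,smoking,5.4
2020,M,25-34,t2d,1.7
2020,M,35-44,t2d,3.4
2020,M,45-54,t2d,8.0
2020,M,55-64,t2d,15.8
2020,M,65-74,t2d,22.6
2020,M,75+,t2d,24.6
2020,W,25-34,t2d,2.2
2020,W,35-44,t2d,3.8
2020,W,45-54,t2d,7.8
2020,W,55-64,t2d,16.0
2020,W,65-74,t2d,22.8
2020,W,75+,t2d,22.7
2020,M,25-34,obesity,20.1
2020,M,35-44,obesity,25.9
2020,M,45-54,obesity,25.5
2020,M,55-64,obesity,24.4
2020,M,65-74,obesity,19.7
2020,M,75+,obesity,14.2
2020,W,25-34,obesity,18.0
2020,W,35-44,obesity,22.4
2020,W,45-54,obesity,23.1
2020,W,55-64,obesity,23.5
2020,W,65-74,obesity,23.7
2020,W,75+,obesity,20.8
2020,M,25-34,smoking,12.8
2020,M,35-44,smoking,11.4
2020,M,45-54,smoking,15.2
2020,M,55-64,smoking,15.4
2020,M,65-74,smoking,11.2
2020,M,75+,smoking,6.5
2020,W,25-34,smoking,5.5
2020,W,35-44,smoking,7.4
2020,W,45-54,smoking,11.4
2020,W,55-64,smoking,10.6
2020,W,65-74,smoking,6.4
2020,W,75+,smoking,4.4
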