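bird,tag,trip,duration_days,max_distance_km,complete
E0368,Axy5,1,4.7,NA,TRUE
E0487,PathTrack,1,9.2,1493,TRUE
E0243,PathTrack,1,12.5,1503,TRUE
E0362,Axy5,1,2.9,NA,TRUE
E0161,PathTrack,1,9.8,1100,TRUE
E0220,AxyTrek,1,1.0,549,FALSE
E0171,AxyTrek,1,0.8,1075,FALSE
E0801,PathTrack,1,1.9,232,TRUE
E0801,PathTrack,2,12.7,1433,TRUE
E0363,PathTrack,1,13.9,1003,TRUE
E0484,PathTrack,1,5.9,675,TRUE
C0888,AxyTrek,1,0.2,231,FALSE
C0901,Axy5,1,6.9,NA,TRUE
E0083,Axy5,1,8.1,NA,FALSE
C1036,Axy5,1,6.4,NA,FALSE
E0552,PathTrack,1,7.9,1241,TRUE
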