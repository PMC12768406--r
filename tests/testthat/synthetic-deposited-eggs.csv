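Night,Moth,ClusterID,DistCm,EggCount,SpeakerEnd
1,f1,k1,-70,40,left
1,f1,k2,5,12,left
2,f1,k3,-68,55,right
2,f1,k4,0,20,right
1,f2,k5,30,8,left
2,f2,k6,74,90,right
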