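recording_id,speaker_id,role,onset_s,offset_s,text
r1,C1,focal_child,0.5,1.5,Look at this.
r1,T1,teacher,2.0,4.0,You are right.
r1,C1,focal_child,5.0,6.0,I have green scissors.
r1,T1,teacher,7.0,10.0,You can use the mirror if you need it.
r1,C1,focal_child,11.0,12.0,okay
r1,T1,teacher,13.0,15.0,I am going to read you something.
r1,C1,focal_child,16.0,17.0,Read it now.
r1,T1,teacher,18.0,20.0,"I do not know if I have green scissors, but I have pink ones."
r1,C2,peer,40.0,41.0,Can I play.
r1,C2,peer,42.0,43.0,My turn.
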