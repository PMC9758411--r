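study,modality,cohort,subgroup,n,mean_deg,sd_deg
Matsumura,ct,living,all,410,26,11
Symeonides,ct,living,stable,80,16.1,11.07
Symeonides,ct,living,unstable,80,4.3,10.56
Myers (B&G CT),ct,living,dominant,24,32.4,11.4
Myers (B&G CT),ct,living,non-dominant,24,25.2,7.7
Oh (B&G CT),ct,living,all,28,31.42,12.1
Oh (CT),ct,living,variant 1,28,29.7,11.66
Oh (CT),ct,living,variant 2,28,30.64,11.24
Oh (CT),ct,living,variant 3,28,30.41,11.17
Oh (CT),ct,living,variant 4,28,32.14,11.7
Myers (CT),ct,living,dominant,24,68.3,14.2
Myers (CT),ct,living,non-dominant,24,52.5,12.6
Chu,ct,living,all,28,41.1,17.1
Raniga,ct,cadaveric,normal,59,36,12
Raniga,ct,living,Walch type B,59,14,9
Daehnert,ct,living,right,50,55.6,
Daehnert,ct,living,left,50,54.6,
Kronberg,xray,living,dominant,100,33,9.3
Kronberg,xray,living,non-dominant,100,29,8.4
Pieper,xray,living,normal,175,40.1,5.7
Pieper,xray,living,anterior dislocation,175,24.3,10.6
Pieper,xray,living,posterior dislocation,175,55.7,5.1
Cyprien,xray,living,stable right,158,22.2,10.25
Cyprien,xray,living,stable left,158,18,9.41
Cyprien,xray,living,unstable 1 right,158,18.5,10.39
Cyprien,xray,living,unstable 1 left,158,12.9,11.18
Cyprien,xray,living,unstable 2 right,158,18.2,8.12
Cyprien,xray,living,unstable 2 left,158,18.3,11.51
Myers (US),ultrasound,living,dominant,24,74.2,14.5
Myers (US),ultrasound,living,non-dominant,24,61.2,14.4
Yaari,ultrasound,living,dominant,40,20,10
Yaari,ultrasound,living,non-dominant,40,29,12
Hannah,ultrasound,living,sulcus site,30,64.4,9.5
Hannah,ultrasound,living,forearm site,30,63.1,9.6
Dashottar,ultrasound,living,all,49,31.5,7.5
Yoshida,ultrasound,living,dominant,74,68.5,10
Yoshida,ultrasound,living,non-dominant,74,58,8.4
Whiteley,ultrasound,living,dominant,102,18.2,9.6
Whiteley,ultrasound,living,non-dominant,102,19.8,10.8
Ito,ultrasound,living,right,58,15.1,3.9
Ito,ultrasound,living,left,58,15.1,2.9
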