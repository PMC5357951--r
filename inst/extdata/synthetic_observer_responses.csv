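observer_id,group,musician,sample_id,true_class,assigned_class
O01,1,FALSE,S01,STEMI,STEMI
O01,1,FALSE,S02,STEMI,STEMI
O01,1,FALSE,S03,STEMI,STEMI
O01,1,FALSE,S04,PVC,PVC
O01,1,FALSE,S05,PVC,PVC
O01,1,FALSE,S06,PVC,PVC
O01,1,FALSE,S07,AFib,AFib
O01,1,FALSE,S08,AFib,AFib
O01,1,FALSE,S09,AFib,AFib
O01,1,FALSE,S10,Bigeminy,Bigeminy
O01,1,FALSE,S11,Bigeminy,Bigeminy
O01,1,FALSE,S12,Bigeminy,Bigeminy
O02,1,TRUE,S01,STEMI,STEMI
O02,1,TRUE,S02,STEMI,STEMI
O02,1,TRUE,S03,STEMI,STEMI
O02,1,TRUE,S04,PVC,PVC
O02,1,TRUE,S05,PVC,PVC
O02,1,TRUE,S06,PVC,PVC
O02,1,TRUE,S07,AFib,AFib
O02,1,TRUE,S08,AFib,AFib
O02,1,TRUE,S09,AFib,AFib
O02,1,TRUE,S10,Bigeminy,Bigeminy
O02,1,TRUE,S11,Bigeminy,Bigeminy
O02,1,TRUE,S12,Bigeminy,Bigeminy
O03,1,TRUE,S01,STEMI,STEMI
O03,1,TRUE,S02,STEMI,STEMI
O03,1,TRUE,S03,STEMI,STEMI
O03,1,TRUE,S04,PVC,PVC
O03,1,TRUE,S05,PVC,PVC
O03,1,TRUE,S06,PVC,PVC
O03,1,TRUE,S07,AFib,AFib
O03,1,TRUE,S08,AFib,AFib
O03,1,TRUE,S09,AFib,AFib
O03,1,TRUE,S10,Bigeminy,Bigeminy
O03,1,TRUE,S11,Bigeminy,Bigeminy
O03,1,TRUE,S12,Bigeminy,Bigeminy
O04,1,TRUE,S01,STEMI,STEMI
O04,1,TRUE,S02,STEMI,STEMI
O04,1,TRUE,S03,STEMI,STEMI
O04,1,TRUE,S04,PVC,PVC
O04,1,TRUE,S05,PVC,PVC
O04,1,TRUE,S06,PVC,PVC
O04,1,TRUE,S07,AFib,AFib
O04,1,TRUE,S08,AFib,AFib
O04,1,TRUE,S09,AFib,AFib
O04,1,TRUE,S10,Bigeminy,Bigeminy
O04,1,TRUE,S11,Bigeminy,Bigeminy
O04,1,TRUE,S12,Bigeminy,Bigeminy
O05,1,TRUE,S01,STEMI,STEMI
O05,1,TRUE,S02,STEMI,STEMI
O05,1,TRUE,S03,STEMI,STEMI
O05,1,TRUE,S04,PVC,PVC
O05,1,TRUE,S05,PVC,PVC
O05,1,TRUE,S06,PVC,PVC
O05,1,TRUE,S07,AFib,AFib
O05,1,TRUE,S08,AFib,AFib
O05,1,TRUE,S09,AFib,STEMI
O05,1,TRUE,S10,Bigeminy,Bigeminy
O05,1,TRUE,S11,Bigeminy,Bigeminy
O05,1,TRUE,S12,Bigeminy,PVC
O06,1,FALSE,S01,STEMI,STEMI
O06,1,FALSE,S02,STEMI,STEMI
O06,1,FALSE,S03,STEMI,AFib
O06,1,FALSE,S04,PVC,PVC
O06,1,FALSE,S05,PVC,PVC
O06,1,FALSE,S06,PVC,PVC
O06,1,FALSE,S07,AFib,AFib
O06,1,FALSE,S08,AFib,AFib
O06,1,FALSE,S09,AFib,Bigeminy
O06,1,FALSE,S10,Bigeminy,Bigeminy
O06,1,FALSE,S11,Bigeminy,Bigeminy
O06,1,FALSE,S12,Bigeminy,STEMI
O07,1,FALSE,S01,STEMI,STEMI
O07,1,FALSE,S02,STEMI,STEMI
O07,1,FALSE,S03,STEMI,Bigeminy
O07,1,FALSE,S04,PVC,PVC
O07,1,FALSE,S05,PVC,PVC
O07,1,FALSE,S06,PVC,PVC
O07,1,FALSE,S07,AFib,AFib
O07,1,FALSE,S08,AFib,Bigeminy
O07,1,FALSE,S09,AFib,PVC
O07,1,FALSE,S10,Bigeminy,Bigeminy
O07,1,FALSE,S11,Bigeminy,Bigeminy
O07,1,FALSE,S12,Bigeminy,AFib
O08,1,TRUE,S01,STEMI,STEMI
O08,1,TRUE,S02,STEMI,STEMI
O08,1,TRUE,S03,STEMI,PVC
O08,1,TRUE,S04,PVC,PVC
O08,1,TRUE,S05,PVC,PVC
O08,1,TRUE,S06,PVC,PVC
O08,1,TRUE,S07,AFib,AFib
O08,1,TRUE,S08,AFib,AFib
O08,1,TRUE,S09,AFib,PVC
O08,1,TRUE,S10,Bigeminy,Bigeminy
O08,1,TRUE,S11,Bigeminy,PVC
O08,1,TRUE,S12,Bigeminy,STEMI
O09,1,FALSE,S01,STEMI,STEMI
O09,1,FALSE,S02,STEMI,PVC
O09,1,FALSE,S03,STEMI,Bigeminy
O09,1,FALSE,S04,PVC,PVC
O09,1,FALSE,S05,PVC,PVC
O09,1,FALSE,S06,PVC,STEMI
O09,1,FALSE,S07,AFib,AFib
O09,1,FALSE,S08,AFib,AFib
O09,1,FALSE,S09,AFib,PVC
O09,1,FALSE,S10,Bigeminy,Bigeminy
O09,1,FALSE,S11,Bigeminy,PVC
O09,1,FALSE,S12,Bigeminy,STEMI
O10,1,TRUE,S01,STEMI,STEMI
O10,1,TRUE,S02,STEMI,AFib
O10,1,TRUE,S03,STEMI,PVC
O10,1,TRUE,S04,PVC,PVC
O10,1,TRUE,S05,PVC,PVC
O10,1,TRUE,S06,PVC,AFib
O10,1,TRUE,S07,AFib,AFib
O10,1,TRUE,S08,AFib,PVC
O10,1,TRUE,S09,AFib,STEMI
O10,1,TRUE,S10,Bigeminy,Bigeminy
O10,1,TRUE,S11,Bigeminy,STEMI
O10,1,TRUE,S12,Bigeminy,AFib
O11,2,TRUE,S01,STEMI,STEMI
O11,2,TRUE,S02,STEMI,STEMI
O11,2,TRUE,S03,STEMI,STEMI
O11,2,TRUE,S04,PVC,PVC
O11,2,TRUE,S05,PVC,PVC
O11,2,TRUE,S06,PVC,PVC
O11,2,TRUE,S07,AFib,AFib
O11,2,TRUE,S08,AFib,AFib
O11,2,TRUE,S09,AFib,AFib
O11,2,TRUE,S10,Bigeminy,Bigeminy
O11,2,TRUE,S11,Bigeminy,Bigeminy
O11,2,TRUE,S12,Bigeminy,STEMI
O12,2,FALSE,S01,STEMI,STEMI
O12,2,FALSE,S02,STEMI,STEMI
O12,2,FALSE,S03,STEMI,AFib
O12,2,FALSE,S04,PVC,PVC
O12,2,FALSE,S05,PVC,PVC
O12,2,FALSE,S06,PVC,PVC
O12,2,FALSE,S07,AFib,AFib
O12,2,FALSE,S08,AFib,AFib
O12,2,FALSE,S09,AFib,AFib
O12,2,FALSE,S10,Bigeminy,Bigeminy
O12,2,FALSE,S11,Bigeminy,Bigeminy
O12,2,FALSE,S12,Bigeminy,AFib
O13,2,TRUE,S01,STEMI,STEMI
O13,2,TRUE,S02,STEMI,STEMI
O13,2,TRUE,S03,STEMI,Bigeminy
O13,2,TRUE,S04,PVC,PVC
O13,2,TRUE,S05,PVC,PVC
O13,2,TRUE,S06,PVC,PVC
O13,2,TRUE,S07,AFib,AFib
O13,2,TRUE,S08,AFib,AFib
O13,2,TRUE,S09,AFib,STEMI
O13,2,TRUE,S10,Bigeminy,Bigeminy
O13,2,TRUE,S11,Bigeminy,Bigeminy
O13,2,TRUE,S12,Bigeminy,PVC
O14,2,FALSE,S01,STEMI,STEMI
O14,2,FALSE,S02,STEMI,STEMI
O14,2,FALSE,S03,STEMI,PVC
O14,2,FALSE,S04,PVC,PVC
O14,2,FALSE,S05,PVC,PVC
O14,2,FALSE,S06,PVC,PVC
O14,2,FALSE,S07,AFib,AFib
O14,2,FALSE,S08,AFib,AFib
O14,2,FALSE,S09,AFib,PVC
O14,2,FALSE,S10,Bigeminy,Bigeminy
O14,2,FALSE,S11,Bigeminy,Bigeminy
O14,2,FALSE,S12,Bigeminy,AFib
O15,2,TRUE,S01,STEMI,STEMI
O15,2,TRUE,S02,STEMI,PVC
O15,2,TRUE,S03,STEMI,Bigeminy
O15,2,TRUE,S04,PVC,PVC
O15,2,TRUE,S05,PVC,PVC
O15,2,TRUE,S06,PVC,PVC
O15,2,TRUE,S07,AFib,AFib
O15,2,TRUE,S08,AFib,AFib
O15,2,TRUE,S09,AFib,STEMI
O15,2,TRUE,S10,Bigeminy,Bigeminy
O15,2,TRUE,S11,Bigeminy,STEMI
O15,2,TRUE,S12,Bigeminy,AFib
O16,2,TRUE,S01,STEMI,STEMI
O16,2,TRUE,S02,STEMI,AFib
O16,2,TRUE,S03,STEMI,PVC
O16,2,TRUE,S04,PVC,PVC
O16,2,TRUE,S05,PVC,PVC
O16,2,TRUE,S06,PVC,AFib
O16,2,TRUE,S07,AFib,AFib
O16,2,TRUE,S08,AFib,PVC
O16,2,TRUE,S09,AFib,STEMI
O16,2,TRUE,S10,Bigeminy,Bigeminy
O16,2,TRUE,S11,Bigeminy,Bigeminy
O16,2,TRUE,S12,Bigeminy,PVC
O17,2,FALSE,S01,STEMI,STEMI
O17,2,FALSE,S02,STEMI,Bigeminy
O17,2,FALSE,S03,STEMI,AFib
O17,2,FALSE,S04,PVC,PVC
O17,2,FALSE,S05,PVC,PVC
O17,2,FALSE,S06,PVC,Bigeminy
O17,2,FALSE,S07,AFib,AFib
O17,2,FALSE,S08,AFib,Bigeminy
O17,2,FALSE,S09,AFib,PVC
O17,2,FALSE,S10,Bigeminy,Bigeminy
O17,2,FALSE,S11,Bigeminy,PVC
O17,2,FALSE,S12,Bigeminy,STEMI
O18,3,TRUE,S01,STEMI,STEMI
O18,3,TRUE,S02,STEMI,STEMI
O18,3,TRUE,S03,STEMI,AFib
O18,3,TRUE,S04,PVC,PVC
O18,3,TRUE,S05,PVC,PVC
O18,3,TRUE,S06,PVC,PVC
O18,3,TRUE,S07,AFib,AFib
O18,3,TRUE,S08,AFib,AFib
O18,3,TRUE,S09,AFib,AFib
O18,3,TRUE,S10,Bigeminy,Bigeminy
O18,3,TRUE,S11,Bigeminy,Bigeminy
O18,3,TRUE,S12,Bigeminy,Bigeminy
O19,3,TRUE,S01,STEMI,STEMI
O19,3,TRUE,S02,STEMI,AFib
O19,3,TRUE,S03,STEMI,PVC
O19,3,TRUE,S04,PVC,PVC
O19,3,TRUE,S05,PVC,PVC
O19,3,TRUE,S06,PVC,PVC
O19,3,TRUE,S07,AFib,AFib
O19,3,TRUE,S08,AFib,STEMI
O19,3,TRUE,S09,AFib,Bigeminy
O19,3,TRUE,S10,Bigeminy,Bigeminy
O19,3,TRUE,S11,Bigeminy,Bigeminy
O19,3,TRUE,S12,Bigeminy,STEMI
O20,3,TRUE,S01,STEMI,STEMI
O20,3,TRUE,S02,STEMI,STEMI
O20,3,TRUE,S03,STEMI,PVC
O20,3,TRUE,S04,PVC,PVC
O20,3,TRUE,S05,PVC,PVC
O20,3,TRUE,S06,PVC,PVC
O20,3,TRUE,S07,AFib,AFib
O20,3,TRUE,S08,AFib,STEMI
O20,3,TRUE,S09,AFib,Bigeminy
O20,3,TRUE,S10,Bigeminy,Bigeminy
O20,3,TRUE,S11,Bigeminy,AFib
O20,3,TRUE,S12,Bigeminy,PVC
O21,3,FALSE,S01,STEMI,Bigeminy
O21,3,FALSE,S02,STEMI,AFib
O21,3,FALSE,S03,STEMI,PVC
O21,3,FALSE,S04,PVC,PVC
O21,3,FALSE,S05,PVC,PVC
O21,3,FALSE,S06,PVC,AFib
O21,3,FALSE,S07,AFib,AFib
O21,3,FALSE,S08,AFib,PVC
O21,3,FALSE,S09,AFib,STEMI
O21,3,FALSE,S10,Bigeminy,AFib
O21,3,FALSE,S11,Bigeminy,PVC
O21,3,FALSE,S12,Bigeminy,STEMI
O22,3,FALSE,S01,STEMI,PVC
O22,3,FALSE,S02,STEMI,Bigeminy
O22,3,FALSE,S03,STEMI,AFib
O22,3,FALSE,S04,PVC,PVC
O22,3,FALSE,S05,PVC,AFib
O22,3,FALSE,S06,PVC,STEMI
O22,3,FALSE,S07,AFib,Bigeminy
O22,3,FALSE,S08,AFib,PVC
O22,3,FALSE,S09,AFib,STEMI
O22,3,FALSE,S10,Bigeminy,Bigeminy
O22,3,FALSE,S11,Bigeminy,STEMI
O22,3,FALSE,S12,Bigeminy,AFib
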