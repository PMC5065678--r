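Date,Bed label,MRN,Alarm and Action,Device name
4/20/14 0:00:00,9115-S1,0000000,**PAPd 18 >16 Ended.,PIIC iX: ixsurv006
4/20/14 0:00:00,9115-S1,0000000,**PAPd 18 >16 Generated.,PIIC iX: ixsurv006
4/20/14 0:00:00,9115-S1,0000000,Yellow alarm sound played.,PIIC iX: ixsurv006
4/20/14 0:00:02,9115-S1,0000000,**ABPs 170 >160 Generated.,PIIC iX: ixsurv006
4/20/14 0:01:05,9123-S1,0000000,***Desat 70 < 78 Generated.,PIIC iX: ixsurv005
4/20/14 0:01:05,9123-S1,0000000,Red alarm sound played.,PIIC iX: ixsurv005
4/20/14 0:01:12,9123-S1,0000000,***Desat 73 < 78 ended.,PIIC iX: ixsurv005
4/20/14 0:01:16,9115-S1,0000000,**ABPs 168 >160 Ended.,PIIC iX: ixsurv006
4/20/14 0:01:20,9123-S1,0000000,Silence.,PIIC iX: ixsurv005
4/20/14 0:01:40,9115-S1,0000000,*Multiform PVCs Generated.,PIIC iX: ixsurv006
4/20/14 0:01:40,9115-S1,0000000,Resume All Alarms.,PIIC iX: ixsurv006
4/20/14 0:01:40,9117-S1,0000000,**RR 37 >30 Ended.,PIIC iX: ixsurv006
4/20/14 0:01:40,9111-S1,0000000,Patient transferred to 9035-S1.,PIIC iX: ixsurv006
4/20/14 0:01:42,9095-S1,0000000,Patient category set to Adult.,PIIC iX: ixsurv006
4/20/14 0:01:43,9090-S1,0000000,Pacer algorithm set to Pacer Algorithm On.,PIIC iX: ixsurv006
4/20/14 0:01:44,9123-S1,0000000,ECG Leads Off Generated.,PIIC iX: ixsurv006
4/20/14 0:01:44,9123-S1,0000000,INOP sound played.,PIIC iX: ixsurv006
4/20/14 0:01:59,9123-S1,0000000,ECG Leads Off Ended.,PIIC iX: ixsurv006
4/20/14 0:02:00,9093-S1,0000000,Equipment Offline.,PIIC iX: ixsurv006
4/20/14 0:02:00,9115-S1,0000000,**PAPd 18 >16 Generated.,PIIC iX: ixsurv006
4/20/14 0:02:00,9093-S1,0000000,Equipment Online.,PIIC iX: ixsurv006
4/20/14 0:02:00,9085-S1,0000000,ST: Al. Limits ST-V2 High: 1.6 ST-V2 Low: −1.6.,PIIC iX: ixsurv006
4/20/14 0:02:00,9117-S1,0000000,Arrhythmia Off.,PIIC iX: ixsurv006
4/20/14 0:02:02,9115-S1,0000000,Pause All Alarms.,PIIC iX: ixsurv006
4/20/14 0:02:02,9075-S1,0000000,Arrhy: Missed Beat Off.,PIIC iX: ixsurv006
4/20/14 0:03:00,9085-S1,0000000,SpO_2_: Desat Limit 78.,PIIC iX: ixsurv006
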