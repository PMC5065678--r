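Date,Bed label,Alarm and Action,Device name
7/16/14 4:57,9101-S1,*** Desat 89 < 90 Generated.,PIIC iX: ixsurv007
7/28/14 21:44,9115-S1,*** Desat 87 < 88 Generated.,PIIC iX: ixsurv006
7/30/14 1:24,9109-S1,*** Desat 8 < 80 Generated.,PIIC iX: ixsurv006
8/11/14 11:59,9097-S1,*** Desat 44 < 50 Generated.,PIIC iX: ixsurv007
8/12/14 10:43,9113-S1,*** Desat 80 < 83 Generated.,PIIC iX: ixsurv006
9/5/14 21:38,9123-S1,*** Desat 0 < 78 Generated.,PIIC iX: ixsurv005
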