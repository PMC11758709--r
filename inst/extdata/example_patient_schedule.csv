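patient_id,vid,aid,reason,location,scheduled_on,scheduled_for,canceled_on,rescheduled_on,arrived_on
P001,VID-1,AID-1,New consult,Hospital A - 2nd FL,2023-01-01,2023-01-05,,,2023-01-05
P001,VID-1,AID-2,Colon screening,Hospital B - Ground,2023-01-01,2023-02-01,2023-01-17,,
P001,VID-2,AID-3,Skin check,Hospital B - Ground,2023-01-03,2023-01-10,,,2023-01-10
P001,VID-3,AID-4,Echocardiogram,Hospital A - Ground,2023-01-05,2023-01-20,,,2023-01-20
P001,VID-4,AID-5,Breast MRI,Hospital A - Ground,2023-01-10,2023-01-15,,,2023-01-15
P001,VID-5,AID-6,Left breast mass - mammogram,Hospital A - 2nd FL,2023-01-15,2023-01-15,,,2023-01-15
P001,VID-6,AID-7,Follow up,Hospital A - 2nd FL,2023-02-01,2023-02-20,,2023-02-10,
P001,VID-6,AID-8,Follow up,Hospital A - 2nd FL,2023-02-10,2023-02-25,,,2023-02-25
P001,VID-7,AID-9,Treatment,Infusion Center - 2nd FL,2023-04-01,2023-04-05,,,2023-04-05
P001,VID-7,AID-10,Treatment,Infusion Center - 2nd FL,2023-04-01,2023-04-06,,,2023-04-06
P001,VID-7,AID-11,Treatment,Infusion Center - 2nd FL,2023-04-01,2023-04-07,,,2023-04-07
P001,VID-7,AID-12,Treatment,Infusion Center - 2nd FL,2023-04-01,2023-04-08,,,2023-04-08
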