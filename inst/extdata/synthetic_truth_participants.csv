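participant_id,true_ability,true_delay_ms
P00001,0.902574660076253,726.15746112798
P00002,0.657228170224156,626.80614667425
P00003,0.673301366490703,920.28794309048
P00004,0.798496356279055,856.762735669421
P00005,0.311061101238701,912.956204012042
P00006,0.323255491777731,954.642109930915
P00007,0.905294296698164,1028.50765822001
P00008,0.846657428471556,879.686663009363
P00009,0.412206864287605,1503.90950666574
P00010,0.779745935985549,965.677401635323
P00011,0.848985168593815,962.434728397209
P00012,0.457995426969959,863.789363943548
P00013,0.496863744797896,563.432891387953
P00014,0.61704908561021,629.029057360377
P00015,0.874871830255696,1061.46090285557
P00016,0.533246757873019,882.368361935601
P00017,0.872304185010659,715.706014825586
P00018,0.682817135985983,590.412652408346
P00019,0.787587012424659,661.44554755421
P00020,0.617846588954345,842.40426141634
P00021,0.578246992950756,717.251120753119
P00022,0.508369728740498,869.876919439179
P00023,0.370210132806901,739.617907635185
P00024,0.752448652422112,777.3446674363
P00025,0.820543610175883,788.364874653591
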