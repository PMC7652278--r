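system,year,batch,map
our,2013,1,0.0822
our,2013,2,0.0631
our,2013,3,0.0795
our,2014,1,0.0892
our,2014,2,0.0656
our,2014,3,0.0795
our,2014,4,0.0743
our,2014,5,0.0668
our,2015,1,0.0724
our,2015,2,0.0931
our,2015,3,0.1048
our,2015,4,0.1056
our,2015,5,0.1412
CNN,2013,1,0.0642
CNN,2013,2,0.0450
CNN,2013,3,0.0559
CNN,2014,1,0.0524
CNN,2014,2,0.0478
CNN,2014,3,0.0465
CNN,2014,4,0.0482
CNN,2014,5,0.0482
CNN,2015,1,0.0374
CNN,2015,2,0.0589
CNN,2015,3,0.0762
CNN,2015,4,0.0945
CNN,2015,5,0.1190
RNN,2013,1,0.0675
RNN,2013,2,0.0486
RNN,2013,3,0.0568
RNN,2014,1,0.0568
RNN,2014,2,0.0493
RNN,2014,3,0.0483
RNN,2014,4,0.0490
RNN,2014,5,0.0476
RNN,2015,1,0.0397
RNN,2015,2,0.0603
RNN,2015,3,0.0824
RNN,2015,4,0.0938
RNN,2015,5,0.1052
LSTM,2013,1,0.0694
LSTM,2013,2,0.0497
LSTM,2013,3,0.0582
LSTM,2014,1,0.0571
LSTM,2014,2,0.0506
LSTM,2014,3,0.0498
LSTM,2014,4,0.0503
LSTM,2014,5,0.0485
LSTM,2015,1,0.0416
LSTM,2015,2,0.0641
LSTM,2015,3,0.0863
LSTM,2015,4,0.0976
LSTM,2015,5,0.1131
RAE,2013,1,0.0736
RAE,2013,2,0.0523
RAE,2013,3,0.0637
RAE,2014,1,0.0783
RAE,2014,2,0.0612
RAE,2014,3,0.0624
RAE,2014,4,0.0617
RAE,2014,5,0.0523
RAE,2015,1,0.0539
RAE,2015,2,0.0685
RAE,2015,3,0.0932
RAE,2015,4,0.0960
RAE,2015,5,0.1203
QL,2013,1,0.0564
QL,2013,2,0.0354
QL,2013,3,0.0536
QL,2014,1,0.0586
QL,2014,2,0.0465
QL,2014,3,0.0542
QL,2014,4,0.0510
QL,2014,5,0.0518
QL,2015,1,0.0386
QL,2015,2,0.0594
QL,2015,3,0.0856
QL,2015,4,0.0895
QL,2015,5,0.1178
SDM,2013,1,0.0583
SDM,2013,2,0.0372
SDM,2013,3,0.0548
SDM,2014,1,0.0650
SDM,2014,2,0.0478
SDM,2014,3,0.0563
SDM,2014,4,0.0536
SDM,2014,5,0.0523
SDM,2015,1,0.0429
SDM,2015,2,0.0648
SDM,2015,3,0.0895
SDM,2015,4,0.0928
SDM,2015,5,0.1201
BM25,2013,1,0.0546
BM25,2013,2,0.0360
BM25,2013,3,0.0527
BM25,2014,1,0.0524
BM25,2014,2,0.0450
BM25,2014,3,0.0517
BM25,2014,4,0.0493
BM25,2014,5,0.0529
BM25,2015,1,0.0378
BM25,2015,2,0.0592
BM25,2015,3,0.0873
BM25,2015,4,0.0864
BM25,2015,5,0.1165
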