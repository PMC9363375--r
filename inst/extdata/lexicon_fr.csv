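number,word,phones
1,un,9~
2,deux,d 2
3,trois,t R w a
4,quatre,k a t R
5,cinq,s E~ k
6,six,s i s
7,sept,s E t
8,huit,8 i t
9,neuf,n 9 f
10,dix,d i s
11,onze,O~ z
12,douze,d u z
13,treize,t R E z
14,quatorze,k a t O R z
15,quinze,k E~ z
16,seize,s E z
17,dix-sept,d i s E t
18,dix-huit,d i z 8 i t
19,dix-neuf,d i z n 9 f
20,vingt,v E~
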