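accession	country	genome_size	helitron_count	density	flowering_time
Col-0	USA	121	665	5.4959	intermediate
Can-0	Spain	119.3	590	4.9455	late
Zu-0	Switzerland	119.7	590	4.9290	late
Po-0	Germany	120.5	593	4.9212	intermediate
Hi-0	Netherlands	120.3	592	4.9210	intermediate
Oy-0	Norway	119.5	575	4.8117	intermediate
Wu-0	Germany	119.7	572	4.7786	intermediate
Sf-2	Spain	119.6	567	4.7408	late
Ct-1	Italy	119.6	567	4.7408	intermediate
Mt-0	Libya	119.5	565	4.7280	intermediate
Edi-0	UK	119.8	564	4.7078	late
Tsu-0	Japan	119.6	559	4.6739	intermediate
Bur-0	Ireland	119.7	556	4.6449	intermediate
Rsch-4	Russia	119.8	554	4.6244	intermediate
Ler-0	Poland	119.7	552	4.6115	intermediate
Ws-0	Russia	119.8	547	4.5659	late
Wil-2	Russia	119.5	543	4.5439	intermediate
Kn-0	Lithuania	119.7	542	4.5280	intermediate
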