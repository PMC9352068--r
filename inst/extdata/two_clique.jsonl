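{"tweet_id":"ta1","user_id":"a1","day":1,"is_retweet":false,"root_tweet_id":"ta1","urls":[],"hashtags":[]}
{"tweet_id":"ta1_a2","user_id":"a2","day":1,"is_retweet":true,"root_tweet_id":"ta1","urls":[],"hashtags":[]}
{"tweet_id":"ta1_a3","user_id":"a3","day":1,"is_retweet":true,"root_tweet_id":"ta1","urls":[],"hashtags":[]}
{"tweet_id":"ta1_a4","user_id":"a4","day":1,"is_retweet":true,"root_tweet_id":"ta1","urls":[],"hashtags":[]}
{"tweet_id":"ta1_a5","user_id":"a5","day":1,"is_retweet":true,"root_tweet_id":"ta1","urls":[],"hashtags":[]}
{"tweet_id":"ta2","user_id":"a2","day":2,"is_retweet":false,"root_tweet_id":"ta2","urls":[],"hashtags":[]}
{"tweet_id":"ta2_a1","user_id":"a1","day":2,"is_retweet":true,"root_tweet_id":"ta2","urls":[],"hashtags":[]}
{"tweet_id":"ta2_a3","user_id":"a3","day":2,"is_retweet":true,"root_tweet_id":"ta2","urls":[],"hashtags":[]}
{"tweet_id":"ta2_a4","user_id":"a4","day":2,"is_retweet":true,"root_tweet_id":"ta2","urls":[],"hashtags":[]}
{"tweet_id":"ta2_a5","user_id":"a5","day":2,"is_retweet":true,"root_tweet_id":"ta2","urls":[],"hashtags":[]}
{"tweet_id":"ta3","user_id":"a3","day":3,"is_retweet":false,"root_tweet_id":"ta3","urls":[],"hashtags":[]}
{"tweet_id":"ta3_a1","user_id":"a1","day":3,"is_retweet":true,"root_tweet_id":"ta3","urls":[],"hashtags":[]}
{"tweet_id":"ta3_a2","user_id":"a2","day":3,"is_retweet":true,"root_tweet_id":"ta3","urls":[],"hashtags":[]}
{"tweet_id":"ta3_a4","user_id":"a4","day":3,"is_retweet":true,"root_tweet_id":"ta3","urls":[],"hashtags":[]}
{"tweet_id":"ta3_a5","user_id":"a5","day":3,"is_retweet":true,"root_tweet_id":"ta3","urls":[],"hashtags":[]}
{"tweet_id":"ta4","user_id":"a4","day":4,"is_retweet":false,"root_tweet_id":"ta4","urls":[],"hashtags":[]}
{"tweet_id":"ta4_a1","user_id":"a1","day":4,"is_retweet":true,"root_tweet_id":"ta4","urls":[],"hashtags":[]}
{"tweet_id":"ta4_a2","user_id":"a2","day":4,"is_retweet":true,"root_tweet_id":"ta4","urls":[],"hashtags":[]}
{"tweet_id":"ta4_a3","user_id":"a3","day":4,"is_retweet":true,"root_tweet_id":"ta4","urls":[],"hashtags":[]}
{"tweet_id":"ta4_a5","user_id":"a5","day":4,"is_retweet":true,"root_tweet_id":"ta4","urls":[],"hashtags":[]}
{"tweet_id":"ta5","user_id":"a5","day":5,"is_retweet":false,"root_tweet_id":"ta5","urls":[],"hashtags":[]}
{"tweet_id":"ta5_a1","user_id":"a1","day":5,"is_retweet":true,"root_tweet_id":"ta5","urls":[],"hashtags":[]}
{"tweet_id":"ta5_a2","user_id":"a2","day":5,"is_retweet":true,"root_tweet_id":"ta5","urls":[],"hashtags":[]}
{"tweet_id":"ta5_a3","user_id":"a3","day":5,"is_retweet":true,"root_tweet_id":"ta5","urls":[],"hashtags":[]}
{"tweet_id":"ta5_a4","user_id":"a4","day":5,"is_retweet":true,"root_tweet_id":"ta5","urls":[],"hashtags":[]}
{"tweet_id":"tb1","user_id":"b1","day":11,"is_retweet":false,"root_tweet_id":"tb1","urls":[],"hashtags":[]}
{"tweet_id":"tb1_b2","user_id":"b2","day":11,"is_retweet":true,"root_tweet_id":"tb1","urls":[],"hashtags":[]}
{"tweet_id":"tb1_b3","user_id":"b3","day":11,"is_retweet":true,"root_tweet_id":"tb1","urls":[],"hashtags":[]}
{"tweet_id":"tb1_b4","user_id":"b4","day":11,"is_retweet":true,"root_tweet_id":"tb1","urls":[],"hashtags":[]}
{"tweet_id":"tb1_b5","user_id":"b5","day":11,"is_retweet":true,"root_tweet_id":"tb1","urls":[],"hashtags":[]}
{"tweet_id":"tb2","user_id":"b2","day":12,"is_retweet":false,"root_tweet_id":"tb2","urls":[],"hashtags":[]}
{"tweet_id":"tb2_b1","user_id":"b1","day":12,"is_retweet":true,"root_tweet_id":"tb2","urls":[],"hashtags":[]}
{"tweet_id":"tb2_b3","user_id":"b3","day":12,"is_retweet":true,"root_tweet_id":"tb2","urls":[],"hashtags":[]}
{"tweet_id":"tb2_b4","user_id":"b4","day":12,"is_retweet":true,"root_tweet_id":"tb2","urls":[],"hashtags":[]}
{"tweet_id":"tb2_b5","user_id":"b5","day":12,"is_retweet":true,"root_tweet_id":"tb2","urls":[],"hashtags":[]}
{"tweet_id":"tb3","user_id":"b3","day":13,"is_retweet":false,"root_tweet_id":"tb3","urls":[],"hashtags":[]}
{"tweet_id":"tb3_b1","user_id":"b1","day":13,"is_retweet":true,"root_tweet_id":"tb3","urls":[],"hashtags":[]}
{"tweet_id":"tb3_b2","user_id":"b2","day":13,"is_retweet":true,"root_tweet_id":"tb3","urls":[],"hashtags":[]}
{"tweet_id":"tb3_b4","user_id":"b4","day":13,"is_retweet":true,"root_tweet_id":"tb3","urls":[],"hashtags":[]}
{"tweet_id":"tb3_b5","user_id":"b5","day":13,"is_retweet":true,"root_tweet_id":"tb3","urls":[],"hashtags":[]}
{"tweet_id":"tb4","user_id":"b4","day":14,"is_retweet":false,"root_tweet_id":"tb4","urls":[],"hashtags":[]}
{"tweet_id":"tb4_b1","user_id":"b1","day":14,"is_retweet":true,"root_tweet_id":"tb4","urls":[],"hashtags":[]}
{"tweet_id":"tb4_b2","user_id":"b2","day":14,"is_retweet":true,"root_tweet_id":"tb4","urls":[],"hashtags":[]}
{"tweet_id":"tb4_b3","user_id":"b3","day":14,"is_retweet":true,"root_tweet_id":"tb4","urls":[],"hashtags":[]}
{"tweet_id":"tb4_b5","user_id":"b5","day":14,"is_retweet":true,"root_tweet_id":"tb4","urls":[],"hashtags":[]}
{"tweet_id":"tb5","user_id":"b5","day":15,"is_retweet":false,"root_tweet_id":"tb5","urls":[],"hashtags":[]}
{"tweet_id":"tb5_b1","user_id":"b1","day":15,"is_retweet":true,"root_tweet_id":"tb5","urls":[],"hashtags":[]}
{"tweet_id":"tb5_b2","user_id":"b2","day":15,"is_retweet":true,"root_tweet_id":"tb5","urls":[],"hashtags":[]}
{"tweet_id":"tb5_b3","user_id":"b3","day":15,"is_retweet":true,"root_tweet_id":"tb5","urls":[],"hashtags":[]}
{"tweet_id":"tb5_b4","user_id":"b4","day":15,"is_retweet":true,"root_tweet_id":"tb5","urls":[],"hashtags":[]}
{"tweet_id":"tx","user_id":"a1","day":20,"is_retweet":false,"root_tweet_id":"tx","urls":[],"hashtags":[]}
{"tweet_id":"tx_rt","user_id":"b1","day":20,"is_retweet":true,"root_tweet_id":"tx","urls":[],"hashtags":[]}
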